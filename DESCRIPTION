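Package: focuscrawl
Title: Focused Web Crawling with Relevance Classification and Web-Graph Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale framework for topical (focused) web crawling and its
    evaluation. Provides a synthetic-web generator with tunable topical link
    locality, an SVM relevance classifier with information-gain feature
    selection and tf-idf (tfc) cosine-normalised term weighting, a priority
    frontier (0-127 scores from four relevance signals) with depth-bounded
    tunneling, per-host politeness scheduling and spider-trap defenses, a
    deterministic fetch-parse-classify-index crawl loop over pluggable
    transports, crawl-quality metrics (harvest rate, seed-target recall,
    inter-rater agreement), and host-aggregated web-graph analysis (PageRank,
    modularity, degree and distance statistics, per-ccTLD publisher rankings).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    methods,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
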