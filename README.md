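# focuscrawl

Focused (topical) web crawling for the consumer-health domain, as a
desk-scale, fully reproducible R framework.

A focused crawler does not traverse the web exhaustively: it classifies each
fetched page for topical relevance and prioritizes the links most likely to
lead to further on-topic pages. `focuscrawl` implements the complete method
stack for such a system and everything needed to evaluate it offline:

- **Synthetic web generator** — an in-memory web of hosts and pages with
  tunable *topical link locality* (the probability that a health page links
  to another health page), informative anchor texts, keyword-bearing URL
  paths, robots.txt rules, deliberately broken markup and spider-trap hosts.
  Because the generator is deterministic under a seed, every component of the
  crawler is testable without touching the network.
- **Relevance classifier** — the standard SVM text-classification pipeline:
  tokenization, case folding, stop-word removal, pluggable stemming;
  feature selection by *information gain*
  `IG(t) = H(C) − P(t)H(C|t) − P(¬t)H(C|¬t)` (base-2, binary term presence);
  *tfc* term weighting `w(t,d) = tf(t,d)·ln(N/df(t))` followed by
  document-wise cosine (L2) normalization; an RBF-kernel SVM (libsvm via
  `e1071`) tuned by k-fold cross-validated grid search on balanced
  80:20-split data, with sigmoid-calibrated class probabilities.
- **Priority frontier** — every discovered URL gets an integer priority in
  `[0, 127]`: `floor(127 · Σ wᵢ sᵢ)` over four signals (source-page class
  probability, same-host indicator, anchor-text relevance, URL n-gram
  relevance). Soft-focused *tunneling* expands bounded chains of irrelevant
  pages (depth `n`, reset on any relevant page); per-host politeness delays,
  per-host page caps and URL shape limits defend against spider traps.
- **Crawl loop** — fetch → tolerant parse (libxml2 recovery) → boilerplate
  removal → classify → index-if-relevant → score and enqueue out-links, over
  a pluggable transport and a virtual clock, so a full crawl is deterministic
  and politeness costs no wall time in tests.
- **Evaluation** — harvest rate `HR(t)` (cumulative fraction of fetched
  pages that are relevant), seed-target recall `|S ∩ T| / |T|` with a
  stratified (largest-remainder, per-ccTLD) seed/target split, and
  inter-rater agreement (pairwise percent agreement, Fleiss κ) for
  human-validated corpora.
- **Host-graph analysis** — page-level link edges collapse to a directed
  simple website graph (one edge per host pair, self-loops dropped); degree
  statistics (E/N plus nonzero-population in/out means), PageRank,
  Louvain-community modularity `Q = Σ(eᵢᵢ − aᵢ²)`, exact BFS diameter and
  average path length, per-ccTLD top-k rankings with publisher-type
  (PI/NPO/PO) tallies.

## Worked example

Generate a small synthetic web, train the classifier, crawl, and analyze
the resulting host graph:

```r
library(focuscrawl)

corpus <- generate_corpus(corpus_config(n_docs_per_class = 500,
                                        overlap_fraction = 0.1,
                                        rng_seed = 42))
web <- generate_web(web_config(n_hosts = 50, topical_locality = 0.8,
                               rng_seed = 42), corpus)
#> <synthetic_web> 50 hosts, 282 pages, 1127 ground-truth links

split <- split_and_balance(corpus, seed = 42)          # balanced 80:20
model <- train_grid_cv(split$train, grid = small_svm_grid(),
                       folds = 5, seed = 42, k = 150)
#> <relevance_model> RBF SVM, 150 features
#>   best C = 0.5, gamma = 0.0078125 (CV accuracy 1, 5-fold)
evaluate_model(model, split$test)
#>      tp    fp    fn    tn accuracy precision recall
#>     100     0     0   100        1         1      1

res <- crawl(web_seed_urls(web), model,
             crawl_config(max_pages = 150, max_tunnel_depth = 2),
             synthetic_transport(web))
glance(res)
#>   n_attempts n_fetched n_indexed n_edges harvest_rate
#>          150       146        74     571        0.507

hs <- harvest_rate(res, interval = 25)
mean_harvest_rate(hs)        # mean of interval-end cumulative rates
#> 0.522

graph_metrics(aggregate_hosts(res$edges))
#> <graph_metrics_report>
#>   nodes 50, edges 476, avg degree 9.52
#>   diameter 3, avg path length 1.672, modularity 0.224
```

Reading the numbers: with a low-overlap vocabulary the classifier separates
the held-out set perfectly (accuracy 1.0 on 200 documents), and the crawl
indexes 74 of 146 fetched pages — a harvest rate around 0.51 on a web where
half the hosts are health-related, with priority steering and tunneling
keeping the crawler inside topical neighborhoods. The host graph aggregated
from the recorded page edges covers all 50 sites.

`autoplot()` methods exist for harvest series, crawl results and host
graphs; `tidy()`/`glance()` methods cover the fitted classifier, crawl
results, graph reports and pipeline runs.

A thin command-line wrapper with subcommands `synth-web`,
`train-classifier`, `crawl`, `eval-crawl`, `graph-metrics` and `run-all`
lives at `inst/cli/focuscrawl.R`:

```sh
Rscript inst/cli/focuscrawl.R run-all --out run1 --seed 7
```

## Scope

The framework is single-process by design: distributed fetching,
JavaScript rendering, live HTTP transports and external storage backends
are out of scope. The synthetic transport is the test implementation of the
fetch interface; a real HTTP adapter can be plugged in without touching the
crawl logic.
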