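# Builders for tiny hand-specified webs and a cached classifier, shared by
# crawler and acceptance tests.

make_test_page_html <- function(text, links = NULL) {
  link_html <- if (!is.null(links) && nrow(links) > 0) {
    paste(sprintf('<a href="%s">%s</a>', links$to, links$anchor),
          collapse = " ")
  } else ""
  paste0('<html><head><title>t</title></head><body>',
         '<nav class="boilerplate">menu ', link_html, '</nav>',
         '<main><p>', text, '</p></main>',
         '<footer class="boilerplate">footer</footer></body></html>')
}

# Build a synthetic_web-compatible object from a tibble of pages
# (url, text, true_class) and an edge tibble (from, to, anchor).
make_test_web <- function(pages, edges,
                          robots = NULL, trap_hosts = character()) {
  host <- sub("^https?://([^/:?#]+).*$", "\\1", pages$url)
  pages <- tibble::tibble(
    url = pages$url, host = host, cctld = focuscrawl::host_cctld(host),
    true_class = pages$true_class,
    doc_id = sprintf("doc%03d", seq_len(nrow(pages))),
    text = pages$text
  )
  pages$html <- vapply(seq_len(nrow(pages)), function(i) {
    mine <- edges[edges$from == pages$url[i], , drop = FALSE]
    make_test_page_html(pages$text[i], mine)
  }, character(1))
  pages$malformed <- FALSE
  hosts <- tibble::tibble(
    host = unique(host), cctld = focuscrawl::host_cctld(unique(host)),
    class = "H", trap = unique(host) %in% trap_hosts,
    has_robots = FALSE
  )
  if (is.null(robots)) {
    robots <- tibble::tibble(host = character(), robots_txt = character())
  }
  structure(list(hosts = hosts, pages = pages, edges = edges,
                 robots = robots, config = NULL),
            class = "synthetic_web")
}

# One well-separated classifier, trained once per test session.
test_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      corpus <- focuscrawl::generate_corpus(
        focuscrawl::corpus_config(n_docs_per_class = 150,
                                  overlap_fraction = 0, rng_seed = 401)
      )
      cache <<- focuscrawl::train_grid_cv(
        corpus, grid = tibble::tibble(cost = 8, gamma = 0.125),
        folds = 5, seed = 402, k = 120
      )
    }
    cache
  }
})

# Corpus documents guaranteed to classify as their class under test_model().
test_doc <- function(class, i = 1) {
  corpus <- focuscrawl::generate_corpus(
    focuscrawl::corpus_config(n_docs_per_class = 150,
                              overlap_fraction = 0, rng_seed = 401)
  )
  corpus$text[corpus$class == class][i]
}
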