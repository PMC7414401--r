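test_that("a two-page relevant web is fully fetched and indexed", {
  pages <- tibble::tibble(
    url = c("http://a.de/one.html", "http://a.de/two.html"),
    text = c(test_doc("H", 1), test_doc("H", 2)),
    true_class = "H"
  )
  edges <- tibble::tibble(from = pages$url[1], to = pages$url[2],
                          anchor = "weiter")
  web <- make_test_web(pages, edges)
  res <- crawl(pages$url[1], test_model(),
               crawl_config(max_pages = 10,
                            politeness = politeness_policy(min_delay = 0)),
               synthetic_transport(web))
  expect_equal(nrow(res$records), 2)
  expect_true(all(res$records$indexed))
  expect_equal(glance(res)$harvest_rate, 1.0)
})

test_that("tunneling with n = 2 crosses an irrelevant page (H -> G -> H)", {
  pages <- tibble::tibble(
    url = sprintf("http://c%d.de/p.html", 1:3),
    text = c(test_doc("H", 3), test_doc("G", 1), test_doc("H", 4)),
    true_class = c("H", "G", "H")
  )
  edges <- tibble::tibble(from = pages$url[1:2], to = pages$url[2:3],
                          anchor = c("mehr", "mehr"))
  web <- make_test_web(pages, edges)
  cfg <- crawl_config(max_pages = 10, max_tunnel_depth = 2,
                      politeness = politeness_policy(min_delay = 0))
  res <- crawl(pages$url[1], test_model(), cfg, synthetic_transport(web))
  expect_equal(nrow(res$records), 3)
  expect_equal(sum(res$records$indexed), 2)
  expect_equal(glance(res)$harvest_rate, 2 / 3)
  # stored depth counts consecutive irrelevant ancestors (excluding self):
  # the G page has a relevant parent (0); the final H page sits behind one
  # irrelevant hop (1)
  rec <- res$records
  expect_equal(rec$tunnel_depth[rec$url == pages$url[2]], 0L)
  expect_equal(rec$tunnel_depth[rec$url == pages$url[3]], 1L)

  # hard-focused (n = 0): the crawl stops at the irrelevant page
  res0 <- crawl(pages$url[1], test_model(),
                crawl_config(max_pages = 10, max_tunnel_depth = 0,
                             politeness = politeness_policy(min_delay = 0)),
                synthetic_transport(web))
  expect_equal(nrow(res0$records), 2)
  expect_false(pages$url[3] %in% res0$records$url)
})

test_that("irrelevant chains are never expanded beyond the tunnel bound", {
  # chain of 5 irrelevant pages behind one relevant seed
  pages <- tibble::tibble(
    url = sprintf("http://h%d.de/p.html", 1:6),
    text = c(test_doc("H", 5), vapply(1:5, function(i) test_doc("G", i + 1),
                                      character(1))),
    true_class = c("H", rep("G", 5))
  )
  edges <- tibble::tibble(from = pages$url[1:5], to = pages$url[2:6],
                          anchor = "mehr")
  web <- make_test_web(pages, edges)
  res <- crawl(pages$url[1], test_model(),
               crawl_config(max_pages = 20, max_tunnel_depth = 2,
                            politeness = politeness_policy(min_delay = 0)),
               synthetic_transport(web))
  # the seed expands; the chain is cut once a page has n = 2 irrelevant
  # ancestors: pages 1..4 fetched, 5..6 never reached
  expect_equal(sort(res$records$url), sort(pages$url[1:4]))
  expect_true(all(res$records$tunnel_depth <= 2))
})

test_that("a robots-blocked seed is recorded but never fetched", {
  pages <- tibble::tibble(url = "http://a.de/private/x.html",
                          text = test_doc("H", 6), true_class = "H")
  web <- make_test_web(pages, tibble::tibble(from = character(),
                                             to = character(),
                                             anchor = character()),
                       robots = tibble::tibble(
                         host = "a.de",
                         robots_txt = "User-agent: *\nDisallow: /private/"
                       ))
  res <- crawl(pages$url, test_model(),
               crawl_config(max_pages = 5,
                            politeness = politeness_policy(min_delay = 0)),
               synthetic_transport(web))
  expect_equal(res$records$status, "robots_blocked")
  expect_equal(sum(res$records$status == "ok"), 0)
})

test_that("transport failures are recorded and the crawl continues", {
  pages <- tibble::tibble(
    url = c("http://a.de/ok.html", "http://b.de/ok.html"),
    text = c(test_doc("H", 7), test_doc("H", 8)),
    true_class = "H"
  )
  # seed list contains a URL the transport cannot resolve
  web <- make_test_web(pages, tibble::tibble(from = character(),
                                             to = character(),
                                             anchor = character()))
  seeds <- c(pages$url[1], "http://gone.de/missing.html", pages$url[2])
  res <- crawl(seeds, test_model(),
               crawl_config(max_pages = 10,
                            politeness = politeness_policy(min_delay = 0)),
               synthetic_transport(web))
  expect_equal(sum(res$records$status == "not_found"), 1)
  expect_equal(sum(res$records$status == "ok"), 2)
})

test_that("no URL is ever dispatched twice and politeness spacing holds", {
  corpus <- generate_corpus(corpus_config(n_docs_per_class = 400,
                                          rng_seed = 61))
  web <- generate_web(web_config(n_hosts = 30, rng_seed = 61), corpus)
  res <- crawl(web_seed_urls(web), test_model(),
               crawl_config(max_pages = 120,
                            politeness = politeness_policy(min_delay = 2)),
               synthetic_transport(web))
  expect_equal(anyDuplicated(res$records$url), 0)
  spacing_ok <- res$dispatch_log |>
    dplyr::group_by(host) |>
    dplyr::summarise(ok = all(diff(sort(time)) >= 2 - 1e-9) | dplyr::n() == 1)
  expect_true(all(spacing_ok$ok))
})

test_that("an unbounded crawl visits exactly the BFS-reachable set", {
  corpus <- generate_corpus(corpus_config(n_docs_per_class = 500,
                                          rng_seed = 71))
  web <- generate_web(web_config(n_hosts = 25, robots_disallow_rate = 0,
                                 malformed_rate = 0, rng_seed = 71), corpus)
  seeds <- web_seed_urls(web)
  res <- crawl(seeds, test_model(),
               crawl_config(max_pages = 5000, max_tunnel_depth = 1000L,
                            allowed_tlds = c(".de", ".at", ".ch", "other"),
                            politeness = politeness_policy(
                              min_delay = 0, per_host_page_cap = 10000)),
               synthetic_transport(web))
  reachable <- oracle_reachable(seeds, web$edges$from, web$edges$to)
  expect_setequal(res$records$url, reachable)
  # recorded edges equal the ground truth restricted to fetched sources
  truth <- web$edges[web$edges$from %in% res$records$url, ]
  expect_setequal(paste(res$edges$from, res$edges$to),
                  paste(truth$from, truth$to))
})

test_that("crawling is deterministic under a fixed configuration", {
  corpus <- generate_corpus(corpus_config(n_docs_per_class = 400,
                                          rng_seed = 81))
  web <- generate_web(web_config(n_hosts = 20, rng_seed = 81), corpus)
  cfg <- crawl_config(max_pages = 60,
                      politeness = politeness_policy(min_delay = 1))
  r1 <- crawl(web_seed_urls(web), test_model(), cfg, synthetic_transport(web))
  r2 <- crawl(web_seed_urls(web), test_model(), cfg, synthetic_transport(web))
  expect_identical(r1$records, r2$records)
  expect_identical(r1$edges, r2$edges)
})
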