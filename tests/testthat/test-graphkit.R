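chain_edges <- function() {
  tibble::tibble(
    from = c("http://a.de/1", "http://b.de/1"),
    to = c("http://b.de/2", "http://c.de/2")
  )
}

test_that("host aggregation collapses pages and drops self-loops", {
  multi <- tibble::tibble(
    from = c("http://a.de/1", "http://a.de/3"),
    to = c("http://b.de/2", "http://b.de/4")
  )
  hg <- aggregate_hosts(multi)
  expect_equal(nrow(hg$edges), 1)  # >= 1 page link collapses to one edge
  expect_equal(hg$edges$from, "a.de")
  intra <- aggregate_hosts(tibble::tibble(from = "http://a.de/1",
                                          to = "http://a.de/2"))
  expect_equal(nrow(intra$nodes), 1)
  expect_equal(nrow(intra$edges), 0)
  hg3 <- aggregate_hosts(chain_edges())
  expect_equal(nrow(hg3$nodes), 3)
  expect_equal(nrow(hg3$edges), 2)
})

test_that("aggregation is idempotent and order-independent", {
  edges <- tibble::tibble(
    from = c("http://a.de/1", "http://b.de/1", "http://a.de/2"),
    to = c("http://b.de/1", "http://c.ch/1", "http://b.de/9")
  )
  a <- aggregate_hosts(edges)
  b <- aggregate_hosts(edges[c(3, 1, 2), ])
  expect_identical(a$nodes, b$nodes)
  expect_identical(dplyr::arrange(a$edges, from, to),
                   dplyr::arrange(b$edges, from, to))
  expect_warning(aggregate_hosts(tibble::tibble(from = "::bad::",
                                                to = "http://a.de/")),
                 "skipped")
})

test_that("degree statistics are exact ratios", {
  hg <- aggregate_hosts(chain_edges())
  st <- degree_stats(hg)
  expect_equal(st$avg_degree, 2 / 3)
  # complete directed graph on 3 nodes
  pairs <- expand.grid(a = c("a.de", "b.de", "c.de"),
                       b = c("a.de", "b.de", "c.de"))
  pairs <- pairs[pairs$a != pairs$b, ]
  full <- aggregate_hosts(tibble::tibble(
    from = sprintf("http://%s/x", pairs$a),
    to = sprintf("http://%s/y", pairs$b)
  ))
  expect_equal(degree_stats(full)$avg_degree, 2)
  # isolated node: a self-loop-only input
  iso <- aggregate_hosts(tibble::tibble(from = "http://a.de/1",
                                        to = "http://a.de/2"))
  expect_equal(degree_stats(iso)$avg_degree, 0)
})

test_that("PageRank is a probability distribution with symmetric limits", {
  cyc2 <- aggregate_hosts(tibble::tibble(
    from = c("http://a.de/", "http://b.de/"),
    to = c("http://b.de/", "http://a.de/")
  ))
  pr <- host_pagerank(cyc2)
  expect_equal(pr$pagerank, c(0.5, 0.5))
  # vertex-transitive: directed 5-cycle is uniform
  hosts <- sprintf("h%d.de", 1:5)
  cyc5 <- aggregate_hosts(tibble::tibble(
    from = sprintf("http://%s/", hosts),
    to = sprintf("http://%s/", hosts[c(2:5, 1)])
  ))
  pr5 <- host_pagerank(cyc5)
  expect_equal(pr5$pagerank, rep(0.2, 5), tolerance = 1e-9)
  expect_equal(sum(pr5$pagerank), 1, tolerance = 1e-9)
  expect_true(all(pr5$pagerank > 0))
})

test_that("PageRank matches a dense power-iteration oracle", {
  # 4-node star: leaves point at the hub (hub is dangling)
  star <- aggregate_hosts(tibble::tibble(
    from = sprintf("http://leaf%d.de/", 1:3),
    to = rep("http://hub.de/", 3)
  ))
  pr <- host_pagerank(star)
  oracle <- oracle_pagerank(star$edges$from, star$edges$to, star$nodes$host)
  expect_equal(pr$pagerank[match(names(oracle), pr$host)],
               unname(oracle), tolerance = 1e-8)

  # random directed graph with dangling nodes
  set.seed(13)
  n <- 40
  hosts <- sprintf("h%02d.de", 1:n)
  e <- tibble::tibble(
    from = sample(hosts[1:30], 120, replace = TRUE),
    to = sample(hosts, 120, replace = TRUE)
  )
  e <- e[e$from != e$to, ]
  hg <- aggregate_hosts(tibble::tibble(from = sprintf("http://%s/", e$from),
                                       to = sprintf("http://%s/", e$to)))
  pr2 <- host_pagerank(hg)
  o2 <- oracle_pagerank(hg$edges$from, hg$edges$to, hg$nodes$host)
  expect_equal(pr2$pagerank[match(names(o2), pr2$host)], unname(o2),
               tolerance = 1e-6)
  expect_equal(sum(pr2$pagerank), 1, tolerance = 1e-9)
})

two_cliques <- function() {
  cl <- function(hosts) {
    p <- expand.grid(a = hosts, b = hosts, stringsAsFactors = FALSE)
    p <- p[p$a < p$b, ]
    tibble::tibble(from = sprintf("http://%s/x", p$a),
                   to = sprintf("http://%s/y", p$b))
  }
  left <- sprintf("l%d.de", 1:5)
  right <- sprintf("r%d.de", 1:5)
  edges <- dplyr::bind_rows(cl(left), cl(right),
                            tibble::tibble(from = "http://l1.de/x",
                                           to = "http://r1.de/y"))
  list(hg = aggregate_hosts(edges), left = left, right = right)
}

test_that("modularity of a supplied partition matches the closed formula", {
  tc <- two_cliques()
  membership <- setNames(
    ifelse(tc$hg$nodes$host %in% tc$left, 1L, 2L), tc$hg$nodes$host
  )
  out <- communities_and_modularity(tc$hg, membership = membership)
  # m = 21 undirected edges; e_ii = 10/21 each; a_i = 21/42 = 1/2
  expect_equal(out$modularity, 2 * (10 / 21 - 0.25), tolerance = 1e-12)
  # single community has Q = 0
  one <- communities_and_modularity(
    tc$hg, membership = setNames(rep(1L, 10), tc$hg$nodes$host)
  )
  expect_equal(one$modularity, 0, tolerance = 1e-12)
})

test_that("detected communities beat the trivial partition and find cliques", {
  tc <- two_cliques()
  det <- communities_and_modularity(tc$hg, seed = 4)
  expect_gte(det$modularity, 0)
  # the two cliques are recovered exactly
  expect_equal(length(unique(det$membership[tc$left])), 1)
  expect_equal(length(unique(det$membership[tc$right])), 1)
  expect_false(det$membership[["l1.de"]] == det$membership[["r1.de"]])
  expect_error(
    communities_and_modularity(
      aggregate_hosts(tibble::tibble(from = "http://a.de/1",
                                     to = "http://a.de/2"))),
    "no edges")
})

test_that("diameter and average path length match enumeration", {
  path4 <- aggregate_hosts(tibble::tibble(
    from = sprintf("http://p%d.de/", 1:3),
    to = sprintf("http://p%d.de/", 2:4)
  ))
  d <- diameter_avg_path(path4)
  expect_equal(d$diameter, 3)
  expect_equal(d$avg_path_length, (2 * (1 + 2 + 3 + 1 + 2 + 1)) / 12)
  cyc4 <- aggregate_hosts(tibble::tibble(
    from = sprintf("http://c%d.de/", 1:4),
    to = sprintf("http://c%d.de/", c(2, 3, 4, 1))
  ))
  expect_equal(diameter_avg_path(cyc4)$diameter, 2)
})

test_that("distances agree with an all-pairs BFS oracle on a random graph", {
  set.seed(23)
  hosts <- sprintf("n%02d.de", 1:50)
  e <- tibble::tibble(from = sample(hosts, 90, replace = TRUE),
                      to = sample(hosts, 90, replace = TRUE))
  e <- dplyr::distinct(e[e$from != e$to, ])
  hg <- aggregate_hosts(tibble::tibble(from = sprintf("http://%s/", e$from),
                                       to = sprintf("http://%s/", e$to)))
  got <- diameter_avg_path(hg)
  # oracle runs on the same largest weak component
  comp <- igraph::components(hg$graph, mode = "weak")
  keep <- names(comp$membership[comp$membership == which.max(comp$csize)])
  sub <- hg$edges[hg$edges$from %in% keep & hg$edges$to %in% keep, ]
  want <- oracle_diameter_avg_path(sub$from, sub$to, keep)
  expect_equal(got$diameter, want$diameter)
  expect_equal(got$avg_path_length, want$avg_path_length, tolerance = 1e-12)
})

test_that("per-ccTLD ranking keeps the top k and tallies publisher types", {
  scores <- tibble::tibble(
    host = c("a.de", "b.de", "c.de", "x.at", "y.at", "z.ch"),
    pagerank = c(0.3, 0.2, 0.1, 0.15, 0.05, 0.2)
  )
  labels <- tibble::tibble(
    host = c("a.de", "b.de", "x.at", "z.ch"),
    publisher_type = c("PI", "NPO", "PO", "PI")
  )
  out <- rank_and_tally(scores, labels, k = 2)
  de <- out$tables[out$tables$cctld == ".de", ]
  expect_equal(de$host, c("a.de", "b.de"))
  expect_equal(de$rank, 1:2)
  expect_false("c.de" %in% out$tables$host)
  overall <- out$shares[out$shares$cctld == "overall", ]
  expect_equal(sum(overall$n), 5)
  expect_equal(overall$n[overall$publisher_type == "PI" &
                           !is.na(overall$publisher_type)], 2)
  # empty input gives empty tables
  empty <- rank_and_tally(tibble::tibble(host = character(),
                                         pagerank = numeric()))
  expect_equal(nrow(empty$tables), 0)
})

test_that("bundled top-25 publisher labels reproduce the printed shares", {
  labels <- read.csv(system.file("extdata", "top25_publishers.csv",
                                 package = "focuscrawl"))
  expect_equal(nrow(labels), 75)
  shares <- publisher_shares(labels)
  overall <- shares[shares$cctld == "overall", ]
  get <- function(t) overall$n[overall$publisher_type == t]
  expect_equal(get("PI"), 30)
  expect_equal(get("NPO"), 19)
  expect_equal(get("PO"), 26)
  de <- shares[shares$cctld == ".de", ]
  expect_equal(de$n[de$publisher_type == "PI"], 12)
  expect_equal(de$n[de$publisher_type == "NPO"], 8)
  expect_equal(de$n[de$publisher_type == "PO"], 5)
})
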