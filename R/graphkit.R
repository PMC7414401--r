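#' Aggregate a page-level link graph to a host graph
#'
#' Collapses page-level hyperlink edges to the website level: one node per
#' distinct hostname and a single directed edge from host A to host B iff at
#' least one page on A links to some page on B. Intra-host links (self-loops
#' after aggregation) are dropped — they carry no inter-site structure.
#' Rows with unparseable URLs are skipped with a warning.
#'
#' @param page_edges Tibble with columns `from` and `to` holding page URLs
#'   (an `anchor` column is ignored), e.g. a crawl's edge list or
#'   [read_edges_tsv()] output.
#' @param node_attrs Optional tibble with a `host` column plus attribute
#'   columns (e.g. `publisher_type`) joined onto the nodes.
#' @return An object of class `host_graph`: list with `graph` (directed
#'   simple igraph), `nodes` (tibble `host`, `cctld`, ...) and `edges`
#'   (tibble `from`, `to` hostnames).
#' @export
aggregate_hosts <- function(page_edges, node_attrs = NULL) {
  from_n <- normalize_url(page_edges$from)
  to_n <- normalize_url(page_edges$to)
  bad <- !from_n$ok | !to_n$ok
  if (any(bad)) {
    warning(sum(bad), " edge row(s) with unparseable URLs skipped")
  }
  eh <- tibble::tibble(from = from_n$host[!bad], to = to_n$host[!bad]) |>
    dplyr::filter(.data$from != .data$to) |>
    dplyr::distinct()
  hosts <- sort(unique(c(from_n$host[!bad], to_n$host[!bad])))
  nodes <- tibble::tibble(host = hosts, cctld = host_cctld(hosts))
  if (!is.null(node_attrs)) {
    nodes <- dplyr::left_join(nodes, node_attrs, by = "host")
  }
  g <- igraph::graph_from_data_frame(eh, directed = TRUE, vertices = nodes)
  structure(list(graph = g, nodes = nodes, edges = eh), class = "host_graph")
}

#' @export
print.host_graph <- function(x, ...) {
  cat("<host_graph> ", nrow(x$nodes), " hosts, ", nrow(x$edges),
      " directed edges\n", sep = "")
  invisible(x)
}

#' Degree statistics of a host graph
#'
#' The average degree of a directed graph is the total number of edges
#' divided by the total number of nodes; averaged over all nodes, the mean
#' in-degree and mean out-degree both equal E/N, so the in/out columns
#' reported here are means over nodes with nonzero in- (respectively out-)
#' degree, alongside the all-nodes value.
#'
#' @param hg A `host_graph`.
#' @return One-row tibble: `n_nodes`, `n_edges`, `avg_degree` (= E/N),
#'   `avg_in_degree`, `avg_out_degree` (nonzero-degree populations),
#'   `avg_in_degree_all`, `avg_out_degree_all`.
#' @export
degree_stats <- function(hg) {
  g <- hg$graph
  n <- igraph::vcount(g)
  if (n == 0) stop_input("empty graph")
  e <- igraph::ecount(g)
  din <- igraph::degree(g, mode = "in")
  dout <- igraph::degree(g, mode = "out")
  nz_mean <- function(d) if (any(d > 0)) mean(d[d > 0]) else 0
  tibble::tibble(
    n_nodes = n, n_edges = e,
    avg_degree = e / n,
    avg_in_degree = nz_mean(din),
    avg_out_degree = nz_mean(dout),
    avg_in_degree_all = mean(din),
    avg_out_degree_all = mean(dout)
  )
}

#' PageRank centrality of hosts
#'
#' Damped random-surfer centrality with uniform teleportation; dangling
#' mass is redistributed uniformly so the scores form a probability
#' distribution (they sum to 1 and are strictly positive for damping < 1).
#'
#' @param hg A `host_graph`.
#' @param damping Damping factor (default 0.85).
#' @return Tibble `host`, `pagerank`, sorted by descending score.
#' @export
host_pagerank <- function(hg, damping = 0.85) {
  pr <- igraph::page_rank(hg$graph, damping = damping, directed = TRUE)$vector
  tibble::tibble(host = names(pr), pagerank = as.numeric(pr)) |>
    dplyr::arrange(dplyr::desc(.data$pagerank), .data$host)
}

#' Community detection and modularity
#'
#' Greedy multilevel (Louvain) modularity maximization on the undirected
#' collapse of the host graph, and Newman modularity
#' `Q = sum_i (e_ii - a_i^2)` of the resulting (or a user-supplied)
#' partition.
#'
#' @param hg A `host_graph` with at least one edge.
#' @param resolution Louvain resolution parameter.
#' @param seed Integer seed (the refinement order is randomized).
#' @param membership Optional named (by host) or node-ordered community
#'   assignment; when given, no detection runs and `Q` is evaluated for
#'   this partition.
#' @return List with `membership` (named integer vector) and `modularity`.
#' @export
communities_and_modularity <- function(hg, resolution = 1.0, seed = 1L,
                                       membership = NULL) {
  if (igraph::ecount(hg$graph) == 0) stop_input("graph has no edges")
  und <- igraph::as_undirected(hg$graph, mode = "collapse")
  if (is.null(membership)) {
    membership <- with_rng(seed, {
      igraph::membership(igraph::cluster_louvain(und, resolution = resolution))
    })
  } else {
    if (!is.null(names(membership))) {
      membership <- membership[igraph::V(und)$name]
    }
    membership <- as.integer(factor(membership))
    names(membership) <- igraph::V(und)$name
  }
  q <- igraph::modularity(und, membership)
  list(membership = membership, modularity = q)
}

#' Diameter and average path length
#'
#' Exact breadth-first-search distances on the undirected collapse of the
#' largest weakly connected component: the diameter is the longest shortest
#' path, the average path length the mean over all reachable ordered pairs.
#' For large graphs a seeded node sample may be used as BFS sources.
#'
#' @param hg A `host_graph` with at least one edge.
#' @param sample_sources `NULL` for exact all-sources BFS, or a count of
#'   randomly sampled source nodes.
#' @param seed Seed for source sampling.
#' @return One-row tibble `diameter`, `avg_path_length`, `component_size`.
#' @export
diameter_avg_path <- function(hg, sample_sources = NULL, seed = 1L) {
  if (igraph::ecount(hg$graph) == 0) stop_input("graph has no edges")
  comp <- igraph::components(hg$graph, mode = "weak")
  keep <- which(comp$membership == which.max(comp$csize))
  sub <- igraph::as_undirected(
    igraph::induced_subgraph(hg$graph, keep), mode = "collapse"
  )
  nv <- igraph::vcount(sub)
  sources <- if (is.null(sample_sources) || sample_sources >= nv) {
    igraph::V(sub)
  } else {
    with_rng(seed, igraph::V(sub)[sample.int(nv, sample_sources)])
  }
  d <- igraph::distances(sub, v = sources, mode = "all")
  vals <- d[is.finite(d) & d > 0]
  tibble::tibble(diameter = max(vals), avg_path_length = mean(vals),
                 component_size = nv)
}

#' Full metrics report for a host graph
#'
#' @param hg A `host_graph` with at least one edge.
#' @param damping PageRank damping factor.
#' @param seed Seed for community detection.
#' @return A list of class `graph_metrics_report` with the degree
#'   statistics, `diameter`, `avg_path_length`, `modularity` and the
#'   PageRank table.
#' @export
graph_metrics <- function(hg, damping = 0.85, seed = 1L) {
  deg <- degree_stats(hg)
  dia <- diameter_avg_path(hg)
  com <- communities_and_modularity(hg, seed = seed)
  structure(
    list(degree = deg, diameter = dia$diameter,
         avg_path_length = dia$avg_path_length,
         modularity = com$modularity,
         pagerank = host_pagerank(hg, damping = damping)),
    class = "graph_metrics_report"
  )
}

#' @export
print.graph_metrics_report <- function(x, ...) {
  cat("<graph_metrics_report>\n")
  cat("  nodes ", x$degree$n_nodes, ", edges ", x$degree$n_edges,
      ", avg degree ", round(x$degree$avg_degree, 3), "\n", sep = "")
  cat("  diameter ", x$diameter, ", avg path length ",
      round(x$avg_path_length, 3), ", modularity ",
      round(x$modularity, 3), "\n", sep = "")
  invisible(x)
}

#' One-row summary of a graph metrics report
#' @param x A `graph_metrics_report`.
#' @param ... Unused.
#' @return Tibble combining degree, distance and modularity figures.
#' @export
glance.graph_metrics_report <- function(x, ...) {
  dplyr::bind_cols(
    x$degree,
    tibble::tibble(diameter = x$diameter,
                   avg_path_length = x$avg_path_length,
                   modularity = x$modularity)
  )
}

#' Top-k hosts per ccTLD and publisher-type shares
#'
#' Ranks hosts by a score (typically PageRank) within each ccTLD, keeping
#' the `k` best (ties broken by hostname), and tallies publisher types —
#' public institution (PI), nonprofit organization (NPO), private
#' organization or individual (PO) — within each table and overall.
#'
#' @param scores Tibble with columns `host` and a score column (second
#'   column or `pagerank`).
#' @param labels Optional tibble `host`, `publisher_type`; unlabeled hosts
#'   tally as `NA`.
#' @param cctld Optional explicit ccTLD per host; derived from the hostname
#'   by default. Unknown TLDs bucket as `"other"`.
#' @param k Table size per ccTLD (default 25).
#' @return List with `tables` (tibble `cctld`, `rank`, `host`, `score`,
#'   `publisher_type`) and `shares` (tibble `cctld` — `"overall"` included —
#'   `publisher_type`, `n`, `share`).
#' @export
rank_and_tally <- function(scores, labels = NULL, cctld = NULL, k = 25L) {
  score_col <- if ("pagerank" %in% names(scores)) "pagerank" else names(scores)[2]
  tab <- tibble::tibble(host = scores$host, score = scores[[score_col]])
  tab$cctld <- if (is.null(cctld)) host_cctld(tab$host) else cctld
  if (!is.null(labels)) {
    tab <- dplyr::left_join(tab, labels[, c("host", "publisher_type")],
                            by = "host")
  } else {
    tab$publisher_type <- NA_character_
  }
  tables <- tab |>
    dplyr::group_by(.data$cctld) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$host, .by_group = TRUE) |>
    dplyr::slice_head(n = k) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("cctld", "rank", "host", "score", "publisher_type")
  shares <- dplyr::bind_rows(
    tables |> dplyr::count(.data$cctld, .data$publisher_type),
    tables |> dplyr::count(.data$publisher_type) |>
      dplyr::mutate(cctld = "overall")
  ) |>
    dplyr::group_by(.data$cctld) |>
    dplyr::mutate(share = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  list(tables = tables, shares = shares)
}

#' Publisher-type shares of pre-ranked tables
#'
#' Tally of PI/NPO/PO shares for already-ranked per-ccTLD host tables (for
#' example a published top-25 list with publisher labels).
#'
#' @param labels Tibble with columns `cctld` and `publisher_type`.
#' @return Tibble `cctld` (including `"overall"`), `publisher_type`, `n`,
#'   `share`.
#' @export
publisher_shares <- function(labels) {
  dplyr::bind_rows(
    labels |> dplyr::count(.data$cctld, .data$publisher_type),
    labels |> dplyr::count(.data$publisher_type) |>
      dplyr::mutate(cctld = "overall")
  ) |>
    dplyr::group_by(.data$cctld) |>
    dplyr::mutate(share = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$cctld, .data$publisher_type)
}

#' Export a host graph as GraphML
#' @param hg A `host_graph`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_host_graph <- function(hg, path) {
  igraph::write_graph(hg$graph, path, format = "graphml")
  invisible(path)
}
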