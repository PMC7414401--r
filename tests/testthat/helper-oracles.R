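# Independent oracles: deliberately naive implementations used only to
# cross-check package results.

# Dense PageRank by explicit power iteration on the Google matrix, with
# uniform teleport and uniform redistribution of dangling mass.
oracle_pagerank <- function(edges_from, edges_to, nodes, damping = 0.85,
                            tol = 1e-12, max_iter = 1000) {
  n <- length(nodes)
  a <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_along(edges_from)) {
    a[edges_from[i], edges_to[i]] <- 1
  }
  out_deg <- rowSums(a)
  p <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    new_p <- rep((1 - damping) / n, n)
    for (i in seq_len(n)) {
      if (out_deg[i] > 0) {
        new_p <- new_p + damping * p[i] * a[i, ] / out_deg[i]
      } else {
        new_p <- new_p + damping * p[i] / n
      }
    }
    if (sum(abs(new_p - p)) < tol) break
    p <- new_p
  }
  stats::setNames(p, nodes)
}

# All-pairs shortest paths by queue-based BFS over an adjacency list
# (undirected), returning diameter and mean over reachable ordered pairs.
oracle_diameter_avg_path <- function(edges_from, edges_to, nodes) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_along(edges_from)) {
    adj[[edges_from[i]]] <- union(adj[[edges_from[i]]], edges_to[i])
    adj[[edges_to[i]]] <- union(adj[[edges_to[i]]], edges_from[i])
  }
  dists <- c()
  for (s in nodes) {
    d <- stats::setNames(rep(Inf, length(nodes)), nodes)
    d[s] <- 0
    queue <- s
    while (length(queue) > 0) {
      u <- queue[1]; queue <- queue[-1]
      for (v in adj[[u]]) {
        if (is.infinite(d[v])) {
          d[v] <- d[u] + 1
          queue <- c(queue, v)
        }
      }
    }
    dists <- c(dists, d[is.finite(d) & d > 0])
  }
  list(diameter = max(dists), avg_path_length = mean(dists))
}

# BFS reachability over a page-level edge list.
oracle_reachable <- function(seeds, edges_from, edges_to) {
  seen <- unique(seeds)
  frontier <- seen
  while (length(frontier) > 0) {
    nxt <- unique(edges_to[edges_from %in% frontier])
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

# Entropy-based information gain from first principles for a single term,
# evaluated by enumerating the four joint counts.
oracle_ig <- function(ph, pg, th, tg) {
  n <- th + tg
  h <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  hc <- h(c(th, tg) / n)
  np <- ph + pg
  na <- n - np
  cond <- 0
  if (np > 0) cond <- cond + np / n * h(c(ph, pg) / np)
  if (na > 0) cond <- cond + na / n * h(c(th - ph, tg - pg) / na)
  hc - cond
}
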