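#' Weights combining the four frontier priority signals
#'
#' A discovered link's priority blends (1) the class probability of the page
#' it was found on, (2) whether it targets the same host, (3) the relevance
#' of its anchor text and (4) the relevance of the URL string itself. The
#' combination is a convex weighted sum scaled to the integer range 0-127.
#'
#' @param prob,host,anchor,url Nonnegative weights; must sum to 1.
#' @return A list of class `priority_weights`.
#' @export
priority_weights <- function(prob = 0.4, host = 0.2, anchor = 0.2, url = 0.2) {
  w <- c(prob = prob, host = host, anchor = anchor, url = url)
  if (any(w < 0)) stop_input("priority weights must be nonnegative")
  if (abs(sum(w) - 1) > 1e-9) stop_input("priority weights must sum to 1")
  structure(as.list(w), class = "priority_weights")
}

#' Per-host politeness and trap-defense policy
#'
#' @param min_delay Minimum time (seconds; virtual in tests) between two
#'   requests to the same host.
#' @param per_host_page_cap Maximum URLs accepted into the frontier per host
#'   (spider-trap defense).
#' @param max_url_length,max_path_depth URL-shape caps forwarded to
#'   [normalize_url()].
#' @return A list of class `politeness_policy`.
#' @export
politeness_policy <- function(min_delay = 1, per_host_page_cap = 100L,
                              max_url_length = 2048L, max_path_depth = 20L) {
  if (min_delay < 0) stop_input("min_delay must be nonnegative")
  check_count(per_host_page_cap, "per_host_page_cap")
  check_count(max_url_length, "max_url_length")
  check_count(max_path_depth, "max_path_depth")
  structure(list(min_delay = min_delay,
                 per_host_page_cap = as.integer(per_host_page_cap),
                 max_url_length = as.integer(max_url_length),
                 max_path_depth = as.integer(max_path_depth)),
            class = "politeness_policy")
}

#' Priority score of a discovered link
#'
#' `floor(127 * sum(w_i * s_i))` clamped to `[0, 127]`; monotone
#' nondecreasing in every signal.
#'
#' @param source_prob_h Class probability of the page the link was found on.
#' @param same_host Logical (or 0/1): does the link target the same host?
#' @param anchor_relevance,url_ngram_relevance Relevance scores in `[0, 1]`
#'   for the anchor text and the URL string.
#' @param weights A [priority_weights()].
#' @return Integer in `[0, 127]` (vectorized).
#' @export
#' @examples
#' score_priority(0.5, TRUE, 0.5, 0.5, priority_weights())
score_priority <- function(source_prob_h, same_host, anchor_relevance,
                           url_ngram_relevance,
                           weights = priority_weights()) {
  same_host <- as.numeric(same_host)
  sig <- cbind(source_prob_h, same_host, anchor_relevance, url_ngram_relevance)
  if (any(is.na(sig)) || any(sig < 0) || any(sig > 1)) {
    stop_input("all priority signals must lie in [0, 1]")
  }
  score <- sig %*% c(weights$prob, weights$host, weights$anchor, weights$url)
  as.integer(pmin(127L, pmax(0L, floor(127 * score))))
}

#' Tunneling decision for a fetched page
#'
#' Soft-focused crawling: links on an irrelevant page are still expanded as
#' long as the chain of consecutive irrelevant ancestors is shorter than
#' `n`; a relevant page resets the chain. With `n = 0` the crawl is
#' hard-focused and never expands an irrelevant page.
#'
#' @param page_relevant Was the fetched page classified relevant?
#' @param parent_tunnel_depth Number of consecutive irrelevant ancestors of
#'   this page (0 for a relevant or seed parent).
#' @param n Maximum tunnel depth.
#' @return List with `expand` (logical) and `child_tunnel_depth` (`NA` when
#'   not expanding).
#' @export
tunnel_decision <- function(page_relevant, parent_tunnel_depth, n) {
  if (n < 0) stop_input("maximum tunnel depth n must be nonnegative")
  if (parent_tunnel_depth < 0) stop_input("parent_tunnel_depth must be >= 0")
  if (page_relevant) {
    list(expand = TRUE, child_tunnel_depth = 0L)
  } else if (parent_tunnel_depth < n) {
    list(expand = TRUE, child_tunnel_depth = as.integer(parent_tunnel_depth) + 1L)
  } else {
    list(expand = FALSE, child_tunnel_depth = NA_integer_)
  }
}

#' Create a crawl frontier
#'
#' The frontier holds discovered-but-unfetched URLs with their priorities
#' and enforces three contracts: global URL uniqueness across the frontier
#' and the already-dispatched set, a per-host accepted-URL cap, and per-host
#' politeness spacing at dispatch time. State is environment-backed;
#' [frontier_entries()] returns a tibble snapshot.
#'
#' @param policy A [politeness_policy()].
#' @return An object of class `crawl_frontier`.
#' @export
frontier_new <- function(policy = politeness_policy()) {
  fr <- new.env(parent = emptyenv())
  fr$policy <- policy
  fr$url <- character()
  fr$host <- character()
  fr$priority <- integer()
  fr$tunnel_depth <- integer()
  fr$discovered_from <- character()
  fr$insertion_index <- integer()
  fr$pending <- logical()
  fr$seen <- new.env(parent = emptyenv())       # url -> row index
  fr$host_accepted <- new.env(parent = emptyenv())
  fr$host_last_dispatch <- new.env(parent = emptyenv())
  fr$counter <- 0L
  class(fr) <- "crawl_frontier"
  fr
}

#' @export
print.crawl_frontier <- function(x, ...) {
  cat("<crawl_frontier> ", sum(x$pending), " pending / ", length(x$url),
      " seen URLs\n", sep = "")
  invisible(x)
}

#' Insert a URL into the frontier
#'
#' Duplicates (already pending or already dispatched) are dropped; a
#' rediscovered pending URL keeps the maximum of its old and new priority.
#' Hosts at their accepted-URL cap reject further insertions.
#'
#' @param fr A `crawl_frontier`.
#' @param url Normalized URL.
#' @param host Its hostname.
#' @param priority Integer priority 0-127.
#' @param tunnel_depth Consecutive-irrelevant-ancestor count.
#' @param discovered_from Source URL (`NA` for seeds).
#' @return One of `"accepted"`, `"duplicate"`, `"capped"`.
#' @export
frontier_enqueue <- function(fr, url, host, priority, tunnel_depth = 0L,
                             discovered_from = NA_character_) {
  existing <- get0(url, envir = fr$seen, inherits = FALSE)
  if (!is.null(existing)) {
    if (fr$pending[existing] && priority > fr$priority[existing]) {
      fr$priority[existing] <- as.integer(priority)
    }
    return("duplicate")
  }
  acc <- get0(host, envir = fr$host_accepted, inherits = FALSE) %||% 0L
  if (acc >= fr$policy$per_host_page_cap) return("capped")
  fr$counter <- fr$counter + 1L
  i <- fr$counter
  fr$url[i] <- url
  fr$host[i] <- host
  fr$priority[i] <- as.integer(priority)
  fr$tunnel_depth[i] <- as.integer(tunnel_depth)
  fr$discovered_from[i] <- discovered_from
  fr$insertion_index[i] <- i
  fr$pending[i] <- TRUE
  assign(url, i, envir = fr$seen)
  assign(host, acc + 1L, envir = fr$host_accepted)
  "accepted"
}

host_ready <- function(fr, hosts, now) {
  vapply(hosts, function(h) {
    last <- get0(h, envir = fr$host_last_dispatch, inherits = FALSE)
    is.null(last) || (now - last) >= fr$policy$min_delay
  }, logical(1))
}

#' Dispatch the next URL respecting politeness
#'
#' Returns the highest-priority pending entry whose host is out of its
#' cooldown window at time `now` (ties broken by insertion order, FIFO),
#' marks it dispatched and stamps the host's last-dispatch time. Returns
#' `NULL` when the frontier is empty or every host is cooling down.
#'
#' @param fr A `crawl_frontier`.
#' @param now Current (virtual) time in seconds.
#' @return A one-row list entry or `NULL`.
#' @export
frontier_next_ready <- function(fr, now) {
  idx <- which(fr$pending)
  if (length(idx) == 0) return(NULL)
  ready <- idx[host_ready(fr, fr$host[idx], now)]
  if (length(ready) == 0) return(NULL)
  best <- ready[order(-fr$priority[ready], fr$insertion_index[ready])[1]]
  fr$pending[best] <- FALSE
  assign(fr$host[best], now, envir = fr$host_last_dispatch)
  list(url = fr$url[best], host = fr$host[best],
       priority = fr$priority[best], tunnel_depth = fr$tunnel_depth[best],
       discovered_from = fr$discovered_from[best],
       insertion_index = fr$insertion_index[best])
}

#' Earliest time any pending host leaves its cooldown
#' @param fr A `crawl_frontier`.
#' @param now Current virtual time.
#' @return A time `>= now`, or `Inf` if nothing is pending.
#' @export
frontier_next_ready_time <- function(fr, now) {
  idx <- which(fr$pending)
  if (length(idx) == 0) return(Inf)
  hosts <- unique(fr$host[idx])
  ready_at <- vapply(hosts, function(h) {
    last <- get0(h, envir = fr$host_last_dispatch, inherits = FALSE)
    if (is.null(last)) now else max(now, last + fr$policy$min_delay)
  }, numeric(1))
  min(ready_at)
}

#' Number of pending frontier entries
#' @param fr A `crawl_frontier`.
#' @return Integer count.
#' @export
frontier_size <- function(fr) sum(fr$pending)

#' Tibble snapshot of the frontier
#'
#' @param fr A `crawl_frontier`.
#' @param pending_only Keep only not-yet-dispatched entries (default).
#' @return Tibble with one row per entry.
#' @export
frontier_entries <- function(fr, pending_only = TRUE) {
  keep <- if (pending_only) which(fr$pending) else seq_len(fr$counter)
  tibble::tibble(
    url = fr$url[keep], host = fr$host[keep], priority = fr$priority[keep],
    tunnel_depth = fr$tunnel_depth[keep],
    discovered_from = fr$discovered_from[keep],
    insertion_index = fr$insertion_index[keep],
    pending = fr$pending[keep]
  )
}

#' Checkpoint a frontier to JSONL and restore it
#'
#' One entry object per line, pending entries only; restoring replays the
#' entries through [frontier_enqueue()].
#'
#' @param fr A `crawl_frontier`.
#' @param path File path.
#' @param policy Policy for the restored frontier.
#' @return `write_frontier()`: `path` invisibly; `read_frontier()`: a new
#'   `crawl_frontier`.
#' @export
write_frontier <- function(fr, path) {
  entries <- frontier_entries(fr, pending_only = TRUE)
  lines <- vapply(seq_len(nrow(entries)), function(i) {
    jsonlite::toJSON(as.list(entries[i, ]), auto_unbox = TRUE, na = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_frontier
#' @export
read_frontier <- function(path, policy = politeness_policy()) {
  fr <- frontier_new(policy)
  for (line in readLines(path, warn = FALSE)) {
    e <- jsonlite::fromJSON(line)
    frontier_enqueue(fr, e$url, e$host, e$priority, e$tunnel_depth,
                     e$discovered_from %||% NA_character_)
  }
  fr
}
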