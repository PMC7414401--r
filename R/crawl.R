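#' Crawl settings
#'
#' @param max_pages Page budget: the crawl stops after this many fetch
#'   attempts even if the frontier is not exhausted (the desk-scale analogue
#'   of stopping a long-running crawl manually).
#' @param max_tunnel_depth Maximum chain of consecutive irrelevant pages
#'   expanded (soft-focused crawling; 0 = hard-focused).
#' @param relevance_threshold A fetched page is indexed iff its probability
#'   of class `H` is at least this value (default 0.5). Stricter cuts (e.g.
#'   0.93) are reporting filters applied afterwards, not crawl thresholds.
#' @param weights A [priority_weights()].
#' @param politeness A [politeness_policy()].
#' @param allowed_tlds ccTLD scope of the crawl.
#' @param agent User-agent name checked against robots.txt.
#' @param boilerplate_classes Passed to [parse_page()].
#' @return A list of class `crawl_config`.
#' @export
crawl_config <- function(max_pages = 500L,
                         max_tunnel_depth = 2L,
                         relevance_threshold = 0.5,
                         weights = priority_weights(),
                         politeness = politeness_policy(),
                         allowed_tlds = c(".de", ".at", ".ch"),
                         agent = "focuscrawl",
                         boilerplate_classes = "boilerplate") {
  check_count(max_pages, "max_pages")
  check_count(max_tunnel_depth, "max_tunnel_depth", positive = FALSE)
  check_fraction(relevance_threshold, "relevance_threshold")
  structure(
    list(max_pages = as.integer(max_pages),
         max_tunnel_depth = as.integer(max_tunnel_depth),
         relevance_threshold = relevance_threshold,
         weights = weights, politeness = politeness,
         allowed_tlds = allowed_tlds, agent = agent,
         boilerplate_classes = boilerplate_classes),
    class = "crawl_config"
  )
}

# deterministic small hash for on-demand trap URL minting
det_hash <- function(s) {
  v <- utf8ToInt(s)
  sum(v * (seq_along(v) %% 31 + 1)) %% 99991
}

#' In-memory transport over a synthetic web
#'
#' The test double for live HTTP: serves the generated pages, per-host
#' robots.txt bodies, 404s for unknown URLs — except on spider-trap hosts,
#' where any URL resolves to a dynamically minted page linking to fresh
#' never-seen URLs on the same host (deterministic in the URL).
#'
#' @param web A `synthetic_web` from [generate_web()].
#' @return A list of class `crawl_transport` with functions
#'   `fetch(url)` -> `list(status, html)` and `robots(host)` -> string or
#'   `NA`.
#' @export
synthetic_transport <- function(web) {
  page_index <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(web$pages))) {
    assign(web$pages$url[i], i, envir = page_index)
  }
  robots_index <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(web$robots))) {
    assign(web$robots$host[i], web$robots$robots_txt[i], envir = robots_index)
  }
  trap_hosts <- web$hosts$host[web$hosts$trap]
  g_texts <- web$pages$text[web$pages$true_class == "G"]
  if (length(g_texts) == 0) g_texts <- web$pages$text

  fetch <- function(url) {
    i <- get0(url, envir = page_index, inherits = FALSE)
    if (!is.null(i)) {
      return(list(status = "ok", html = web$pages$html[i]))
    }
    host <- tolower(sub("^https?://([^/:?#]+).*$", "\\1", url))
    if (host %in% trap_hosts) {
      h <- det_hash(url)
      children <- tibble::tibble(
        to = sprintf("http://%s/trap/t%06d.html", host,
                     (h * 7 + 1:3) %% 999983),
        anchor = "archiv seite"
      )
      txt <- g_texts[h %% length(g_texts) + 1]
      return(list(status = "ok",
                  html = render_page_html("archiv", txt, children,
                                          malformed = FALSE)))
    }
    list(status = "not_found", html = NULL)
  }
  robots <- function(host) {
    get0(host, envir = robots_index, inherits = FALSE) %||% NA_character_
  }
  structure(list(fetch = fetch, robots = robots), class = "crawl_transport")
}

url_feature_text <- function(url) {
  path <- sub("^https?://[^/]+", "", url)
  tokens <- stringr::str_split_1(tolower(path), "[^a-z0-9]+")
  tokens <- tokens[nzchar(tokens)]
  grams <- unlist(lapply(tokens, function(t) {
    if (nchar(t) < 3) return(character())
    substring(t, 1:(nchar(t) - 2), 3:nchar(t))
  }), use.names = FALSE)
  paste(c(tokens, grams), collapse = " ")
}

#' Run a focused crawl
#'
#' The fetch-parse-classify-index loop: seeds enter the frontier at maximum
#' priority; each iteration dispatches the highest-priority URL whose host
#' is polite-ready, checks robots.txt, fetches, parses (tolerantly),
#' classifies the boilerplate-free text, applies the tunneling policy and,
#' if expanding, scores and enqueues the page's out-links from the four
#' relevance signals. Every fetch attempt is recorded; every extracted link
#' is recorded as a page-level edge, including edges to pages never
#' fetched. Time is virtual, so politeness delays cost nothing in tests and
#' the crawl is fully deterministic.
#'
#' @param seeds Character vector of seed URLs.
#' @param model A trained `relevance_model`.
#' @param config A [crawl_config()].
#' @param transport A transport such as [synthetic_transport()].
#' @return A list of class `crawl_result`: `records` (one row per fetch
#'   attempt: `fetch_index`, `url`, `host`, `status`, `prob_h`, `relevant`,
#'   `indexed`, `tunnel_depth`, `time`), `edges` (page-level `from`, `to`,
#'   `anchor`), `dispatch_log`, `config`, and `frontier_remaining`.
#' @export
crawl <- function(seeds, model, config = crawl_config(), transport) {
  pol <- config$politeness
  fr <- frontier_new(pol)
  seed_norm <- normalize_url(seeds, allowed_tlds = config$allowed_tlds,
                             max_length = pol$max_url_length,
                             max_path_depth = pol$max_path_depth)
  seed_ok <- seed_norm[seed_norm$ok, ]
  if (nrow(seed_ok) == 0) stop_input("no seed URL survived normalization")
  for (i in seq_len(nrow(seed_ok))) {
    frontier_enqueue(fr, seed_ok$url[i], seed_ok$host[i], priority = 127L,
                     tunnel_depth = 0L)
  }

  records <- vector("list", config$max_pages)
  edge_acc <- vector("list", config$max_pages)
  n_rec <- 0L
  now <- 0
  robots_cache <- new.env(parent = emptyenv())

  get_robots <- function(host) {
    r <- get0(host, envir = robots_cache, inherits = FALSE)
    if (is.null(r)) {
      r <- list(rules = parse_robots(transport$robots(host)))
      assign(host, r, envir = robots_cache)
    }
    r$rules
  }

  while (n_rec < config$max_pages) {
    entry <- frontier_next_ready(fr, now)
    if (is.null(entry)) {
      nxt <- frontier_next_ready_time(fr, now)
      if (!is.finite(nxt)) break
      now <- nxt
      next
    }
    n_rec <- n_rec + 1L
    rec <- list(fetch_index = n_rec, url = entry$url, host = entry$host,
                status = NA_character_, prob_h = NA_real_, relevant = FALSE,
                indexed = FALSE, tunnel_depth = entry$tunnel_depth,
                time = now)

    if (!robots_allowed(get_robots(entry$host), config$agent, entry$url)) {
      rec$status <- "robots_blocked"
      records[[n_rec]] <- rec
      next
    }
    res <- transport$fetch(entry$url)
    if (!identical(res$status, "ok")) {
      rec$status <- res$status %||% "error"
      records[[n_rec]] <- rec
      next
    }
    rec$status <- "ok"
    parsed <- parse_page(res$html, entry$url,
                         boilerplate_classes = config$boilerplate_classes)
    cls <- classify(model, parsed$text)
    rec$prob_h <- cls$prob_h[1]
    rec$relevant <- cls$prob_h[1] >= config$relevance_threshold
    rec$indexed <- rec$relevant                 # irrelevant pages not indexed
    records[[n_rec]] <- rec

    links <- parsed$links[parsed$links$ok & !is.na(parsed$links$url), ]
    if (nrow(links) > 0) {
      edge_acc[[n_rec]] <- tibble::tibble(from = entry$url, to = links$url,
                                          anchor = links$anchor)
    }

    td <- tunnel_decision(rec$relevant, entry$tunnel_depth,
                          config$max_tunnel_depth)
    if (!td$expand || nrow(links) == 0) next

    scoped <- normalize_url(links$url, allowed_tlds = config$allowed_tlds,
                            max_length = pol$max_url_length,
                            max_path_depth = pol$max_path_depth)
    keep <- which(scoped$ok)
    if (length(keep) == 0) next
    anchor_rel <- classify(model, links$anchor[keep])$prob_h
    url_rel <- classify(model,
                        vapply(scoped$url[keep], url_feature_text,
                               character(1)))$prob_h
    pri <- score_priority(rep(rec$prob_h, length(keep)),
                          scoped$host[keep] == entry$host,
                          anchor_rel, url_rel, config$weights)
    for (j in seq_along(keep)) {
      frontier_enqueue(fr, scoped$url[keep[j]], scoped$host[keep[j]],
                       priority = pri[j],
                       tunnel_depth = td$child_tunnel_depth,
                       discovered_from = entry$url)
    }
  }

  records <- dplyr::bind_rows(records[seq_len(n_rec)])
  edges <- dplyr::bind_rows(edge_acc)
  if (nrow(edges) == 0) {
    edges <- tibble::tibble(from = character(), to = character(),
                            anchor = character())
  }
  structure(
    list(records = records,
         edges = edges,
         dispatch_log = records[, c("host", "time")],
         frontier_remaining = frontier_entries(fr),
         config = config),
    class = "crawl_result"
  )
}

#' @export
print.crawl_result <- function(x, ...) {
  n <- nrow(x$records)
  cat("<crawl_result> ", n, " fetch attempts, ",
      sum(x$records$indexed), " indexed, ",
      nrow(x$edges), " page-level edges\n", sep = "")
  invisible(x)
}

#' Tidy a crawl result
#' @param x A `crawl_result`.
#' @param ... Unused.
#' @return The per-fetch records tibble.
#' @export
tidy.crawl_result <- function(x, ...) x$records

#' One-row crawl summary
#' @param x A `crawl_result`.
#' @param ... Unused.
#' @return Tibble with fetch/indexed counts and the final cumulative harvest
#'   rate.
#' @export
glance.crawl_result <- function(x, ...) {
  ok <- x$records$status == "ok"
  tibble::tibble(
    n_attempts = nrow(x$records),
    n_fetched = sum(ok),
    n_indexed = sum(x$records$indexed),
    n_edges = nrow(x$edges),
    harvest_rate = if (any(ok)) sum(x$records$indexed) / sum(ok) else NA_real_
  )
}

#' Write crawl records as JSONL
#'
#' One CrawlRecord object per line in fetch order.
#'
#' @param result A `crawl_result`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_crawl_records <- function(result, path) {
  recs <- result$records
  lines <- vapply(seq_len(nrow(recs)), function(i) {
    jsonlite::toJSON(as.list(recs[i, ]), auto_unbox = TRUE, na = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
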