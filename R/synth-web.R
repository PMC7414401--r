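#' Configuration for the synthetic web generator
#'
#' Describes an in-memory web of hosts and pages whose statistical structure
#' mirrors the assumptions a focused crawler exploits: topical link locality
#' (pages of a topic link mostly to pages of the same topic), informative
#' anchor texts, keyword-bearing URL paths, per-host robots.txt rules, broken
#' markup, and spider-trap hosts that mint unbounded fresh URLs.
#'
#' @param n_hosts Number of websites.
#' @param pages_per_host Length-2 integer range; each host gets a uniformly
#'   drawn page count from this range.
#' @param topical_locality Probability that an out-link from an `H` page
#'   targets another `H` page (and symmetrically for `G` pages).
#' @param frac_health_hosts Fraction of hosts whose pages are health-related.
#' @param cctld_shares Named numeric vector of ccTLD shares over
#'   `.de`, `.at`, `.ch` and `other`; must sum to 1.
#' @param anchor_informativeness Probability that a link's anchor text is
#'   sampled from the target page's document rather than generic navigation
#'   wording.
#' @param url_keyword_rate Probability that a URL path segment is a word from
#'   the page's own document rather than an opaque identifier.
#' @param robots_disallow_rate Fraction of hosts that publish a robots.txt
#'   disallowing their `/private/` subtree (one page per such host lives
#'   there).
#' @param trap_hosts Number of spider-trap hosts: any URL on such a host
#'   resolves to a page linking to never-before-seen URLs on the same host.
#' @param malformed_rate Fraction of pages rendered with deliberately broken
#'   markup (unclosed tags, unquoted attributes).
#' @param out_links_mean Mean out-degree per page (Poisson).
#' @param rng_seed Integer seed; identical configurations generate identical
#'   webs.
#'
#' @return A list of class `web_config`.
#' @export
web_config <- function(n_hosts = 200,
                       pages_per_host = c(3L, 8L),
                       topical_locality = 0.8,
                       frac_health_hosts = 0.5,
                       cctld_shares = c(".de" = 0.85, ".at" = 0.07, ".ch" = 0.08),
                       anchor_informativeness = 0.7,
                       url_keyword_rate = 0.5,
                       robots_disallow_rate = 0.1,
                       trap_hosts = 0L,
                       malformed_rate = 0.1,
                       out_links_mean = 4,
                       rng_seed = 1L) {
  check_count(n_hosts, "n_hosts")
  if (length(pages_per_host) != 2L || any(pages_per_host < 1) ||
      pages_per_host[2] < pages_per_host[1]) {
    stop_input("pages_per_host must be an increasing range of positive counts")
  }
  check_fraction(topical_locality, "topical_locality")
  check_fraction(frac_health_hosts, "frac_health_hosts")
  check_fraction(anchor_informativeness, "anchor_informativeness")
  check_fraction(url_keyword_rate, "url_keyword_rate")
  check_fraction(robots_disallow_rate, "robots_disallow_rate")
  check_fraction(malformed_rate, "malformed_rate")
  check_count(trap_hosts, "trap_hosts", positive = FALSE)
  if (abs(sum(cctld_shares) - 1) > 1e-9) {
    stop_input("cctld_shares must sum to 1, got ", sum(cctld_shares))
  }
  known <- c(".de", ".at", ".ch", "other")
  if (!all(names(cctld_shares) %in% known)) {
    stop_input("cctld_shares names must be among ", paste(known, collapse = ", "))
  }
  structure(
    list(
      n_hosts = as.integer(n_hosts),
      pages_per_host = as.integer(pages_per_host),
      topical_locality = topical_locality,
      frac_health_hosts = frac_health_hosts,
      cctld_shares = cctld_shares,
      anchor_informativeness = anchor_informativeness,
      url_keyword_rate = url_keyword_rate,
      robots_disallow_rate = robots_disallow_rate,
      trap_hosts = as.integer(trap_hosts),
      malformed_rate = malformed_rate,
      out_links_mean = out_links_mean,
      rng_seed = as.integer(rng_seed)
    ),
    class = "web_config"
  )
}

cctld_suffix <- function(cctld) {
  ifelse(cctld == "other", ".com", cctld)
}

generic_anchors <- c("hier klicken", "mehr lesen", "weiter", "zur startseite",
                     "details", "mehr erfahren")

render_page_html <- function(title, text, links, malformed) {
  link_html <- if (nrow(links) > 0) {
    paste(sprintf("<a href=\"%s\">%s</a>", links$to, links$anchor),
          collapse = " | ")
  } else {
    ""
  }
  nav <- paste0("<nav class=\"boilerplate\">Startseite | Impressum | Kontakt | ",
                link_html, "</nav>")
  footer <- paste0("<footer class=\"boilerplate\">Copyright Beispiel Verlag.",
                   " Alle Rechte vorbehalten.</footer>")
  main <- sprintf("<main><p>%s</p></main>", text)
  if (malformed) {
    # unclosed <p>/<main>, unquoted attribute -- must still be parseable in
    # recovery mode
    main <- sprintf("<main><p>%s", text)
    nav <- sub("class=\"boilerplate\"", "class=boilerplate", nav, fixed = TRUE)
  }
  paste0("<html><head><title>", title, "</title></head><body>",
         nav, main, footer, "</body></html>")
}

#' Generate a synthetic web from a labeled corpus
#'
#' Builds hosts, pages, a ground-truth page-level link graph, per-host robots
#' rules and spider-trap hosts. Each page's visible text is one corpus
#' document wrapped in HTML with marked boilerplate blocks; link anchors and
#' URL paths carry topical keywords at configurable rates so that all four
#' frontier priority signals are learnable.
#'
#' @param config A [web_config()].
#' @param corpus A corpus tibble from [generate_corpus()]; must hold at least
#'   one document per generated page in each class.
#' @return A list of class `synthetic_web` with elements `hosts`, `pages`,
#'   `edges` (ground-truth `from`/`to`/`anchor`), `robots` and `config`.
#' @export
generate_web <- function(config, corpus) {
  if (!inherits(config, "web_config")) {
    stop_input("`config` must be created by web_config()")
  }
  with_rng(config$rng_seed, {
    # --- hosts ------------------------------------------------------------
    shares <- config$cctld_shares
    counts <- largest_remainder(config$n_hosts, shares)
    cctld <- rep(names(shares), counts)
    n_h_hosts <- round(config$frac_health_hosts * config$n_hosts)
    host_class <- sample(c(rep("H", n_h_hosts),
                           rep("G", config$n_hosts - n_h_hosts)))
    host <- sprintf("www.site%04d%s", seq_len(config$n_hosts),
                    cctld_suffix(cctld))
    trap <- rep(FALSE, config$n_hosts)
    if (config$trap_hosts > 0) {
      trap[sample(config$n_hosts, min(config$trap_hosts, config$n_hosts))] <- TRUE
    }
    has_robots <- stats::runif(config$n_hosts) < config$robots_disallow_rate
    hosts <- tibble::tibble(host = host, cctld = cctld, class = host_class,
                            trap = trap, has_robots = has_robots)

    # --- assign corpus documents to pages ---------------------------------
    n_pages <- sample(config$pages_per_host[1]:config$pages_per_host[2],
                      config$n_hosts, replace = TRUE)
    need_h <- sum(n_pages[host_class == "H"])
    need_g <- sum(n_pages[host_class == "G"])
    pool_h <- which(corpus$class == "H")
    pool_g <- which(corpus$class == "G")
    if (need_h > length(pool_h) || need_g > length(pool_g)) {
      stop_input("corpus exhausted: need ", need_h, " H and ", need_g,
                 " G documents, corpus has ", length(pool_h), " / ",
                 length(pool_g))
    }
    doc_h <- sample(pool_h, need_h)
    doc_g <- sample(pool_g, need_g)

    path_segment <- function(words, fallback_id) {
      if (length(words) > 0 && stats::runif(1) < config$url_keyword_rate) {
        sample(words, 1)
      } else {
        sprintf("p%05x", fallback_id)
      }
    }

    pages_list <- vector("list", config$n_hosts)
    ih <- 0L; ig <- 0L; uid <- 0L
    for (k in seq_len(config$n_hosts)) {
      np <- n_pages[k]
      if (host_class[k] == "H") {
        idx <- doc_h[ih + seq_len(np)]; ih <- ih + np
      } else {
        idx <- doc_g[ig + seq_len(np)]; ig <- ig + np
      }
      words <- strsplit(corpus$text[idx], " ", fixed = TRUE)
      paths <- vapply(seq_len(np), function(j) {
        uid <<- uid + 1L
        seg <- path_segment(words[[j]], uid)
        prefix <- if (has_robots[k] && j == np && np > 1) "/private" else ""
        sprintf("%s/%s/a%05d.html", prefix, seg, uid)
      }, character(1))
      pages_list[[k]] <- tibble::tibble(
        url = paste0("http://", host[k], paths),
        host = host[k],
        cctld = cctld[k],
        true_class = host_class[k],
        doc_id = corpus$id[idx],
        text = corpus$text[idx]
      )
    }
    pages <- dplyr::bind_rows(pages_list)

    # --- links ------------------------------------------------------------
    is_h_page <- pages$true_class == "H"
    h_idx <- which(is_h_page); g_idx <- which(!is_h_page)
    n_out <- stats::rpois(nrow(pages), config$out_links_mean)
    edge_rows <- vector("list", nrow(pages))
    page_words <- strsplit(pages$text, " ", fixed = TRUE)
    for (i in seq_len(nrow(pages))) {
      if (n_out[i] == 0L) next
      same_topic <- stats::runif(n_out[i]) < config$topical_locality
      want_h <- if (is_h_page[i]) same_topic else !same_topic
      tgt <- integer(n_out[i])
      if (any(want_h)) tgt[want_h] <- sample(h_idx, sum(want_h), replace = TRUE)
      if (any(!want_h)) tgt[!want_h] <- sample(g_idx, sum(!want_h), replace = TRUE)
      keep <- tgt != i
      if (!any(keep)) next
      tgt <- tgt[keep]
      anchors <- vapply(tgt, function(t) {
        if (stats::runif(1) < config$anchor_informativeness) {
          w <- page_words[[t]]
          paste(sample(w, min(3, length(w))), collapse = " ")
        } else {
          sample(generic_anchors, 1)
        }
      }, character(1))
      edge_rows[[i]] <- tibble::tibble(from = pages$url[i],
                                       to = pages$url[tgt],
                                       anchor = anchors)
    }
    edges <- dplyr::bind_rows(edge_rows)
    if (nrow(edges) == 0) {
      edges <- tibble::tibble(from = character(), to = character(),
                              anchor = character())
    }
    # seed entry links for trap hosts so the trap is reachable from its pages
    if (any(trap)) {
      trap_pages <- pages[pages$host %in% host[trap], ]
      if (nrow(trap_pages) > 0) {
        edges <- dplyr::bind_rows(edges, tibble::tibble(
          from = trap_pages$url,
          to = paste0("http://", trap_pages$host, "/trap/t000001.html"),
          anchor = "archiv"
        ))
      }
    }

    # --- render HTML ------------------------------------------------------
    malformed <- stats::runif(nrow(pages)) < config$malformed_rate
    by_from <- split(seq_len(nrow(edges)), factor(edges$from, levels = pages$url))
    pages$html <- vapply(seq_len(nrow(pages)), function(i) {
      render_page_html(pages$doc_id[i], pages$text[i],
                       edges[by_from[[i]], , drop = FALSE], malformed[i])
    }, character(1))
    pages$malformed <- malformed

    robots <- tibble::tibble(
      host = host[has_robots],
      robots_txt = "User-agent: *\nDisallow: /private/\n"
    )

    structure(
      list(hosts = hosts, pages = pages, edges = edges, robots = robots,
           config = config),
      class = "synthetic_web"
    )
  })
}

#' @export
print.synthetic_web <- function(x, ...) {
  cat("<synthetic_web> ", nrow(x$hosts), " hosts, ", nrow(x$pages),
      " pages, ", nrow(x$edges), " ground-truth links\n", sep = "")
  invisible(x)
}

#' Serialize a synthetic web to plain-text files
#'
#' Writes `pages.jsonl` (one page object per line), `edges.tsv`
#' (source, target, anchor), `robots.jsonl` and `seeds.txt` (one URL per
#' host front page) into `dir`.
#'
#' @param web A `synthetic_web`.
#' @param dir Output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_web <- function(web, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  page_lines <- vapply(seq_len(nrow(web$pages)), function(i) {
    jsonlite::toJSON(as.list(web$pages[i, c("url", "host", "cctld",
                                            "true_class", "doc_id", "text",
                                            "html", "malformed")]),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(page_lines, file.path(dir, "pages.jsonl"))
  write_edges_tsv(web$edges, file.path(dir, "edges.tsv"))
  robot_lines <- vapply(seq_len(nrow(web$robots)), function(i) {
    jsonlite::toJSON(as.list(web$robots[i, ]), auto_unbox = TRUE)
  }, character(1))
  writeLines(robot_lines, file.path(dir, "robots.jsonl"))
  writeLines(web_seed_urls(web), file.path(dir, "seeds.txt"))
  invisible(dir)
}

#' Default seed URLs of a synthetic web (first page of every host)
#' @param web A `synthetic_web`.
#' @return Character vector of URLs.
#' @export
web_seed_urls <- function(web) {
  web$pages |>
    dplyr::group_by(.data$host) |>
    dplyr::slice(1) |>
    dplyr::pull("url")
}

#' Write / read a page-level edge list as TSV
#'
#' Columns: source URL, target URL, anchor text (no header).
#'
#' @param edges Tibble with columns `from`, `to` and optionally `anchor`.
#' @param path File path.
#' @return `write_edges_tsv()` returns `path` invisibly; `read_edges_tsv()`
#'   the edges tibble.
#' @export
write_edges_tsv <- function(edges, path) {
  anchor <- if ("anchor" %in% names(edges)) edges$anchor else rep("", nrow(edges))
  writeLines(paste(edges$from, edges$to, anchor, sep = "\t"), path)
  invisible(path)
}

#' @rdname write_edges_tsv
#' @export
read_edges_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) {
    return(tibble::tibble(from = character(), to = character(),
                          anchor = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble::tibble(
    from = vapply(parts, `[`, character(1), 1),
    to = vapply(parts, `[`, character(1), 2),
    anchor = vapply(parts, function(p) if (length(p) >= 3) p[3] else "",
                    character(1))
  )
}
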