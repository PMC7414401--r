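#' Extract the country-code TLD bucket of a hostname
#'
#' @param host Character vector of hostnames.
#' @return One of `".de"`, `".at"`, `".ch"` or `"other"` per host.
#' @export
host_cctld <- function(host) {
  suffix <- stringr::str_extract(tolower(host), "\\.[a-z0-9-]+$")
  out <- rep("other", length(host))
  known <- !is.na(suffix) & suffix %in% c(".de", ".at", ".ch")
  out[known] <- suffix[known]
  out
}

resolve_dot_segments <- function(path) {
  segs <- strsplit(path, "/", fixed = TRUE)[[1]]
  out <- character()
  for (s in segs) {
    if (s == "." || s == "") next
    if (s == "..") {
      if (length(out) > 0) out <- out[-length(out)]
    } else {
      out <- c(out, s)
    }
  }
  trailing <- grepl("/$", path) || grepl("/\\.\\.?$", path)
  paste0("/", paste(out, collapse = "/"), if (trailing && length(out) > 0) "/" else "")
}

normalize_url1 <- function(raw, allowed_tlds, max_length, max_path_depth) {
  rejected <- function(reason) {
    list(url = NA_character_, host = NA_character_, cctld = NA_character_,
         ok = FALSE, reason = reason)
  }
  if (is.na(raw) || !nzchar(trimws(raw))) return(rejected("empty"))
  raw <- trimws(raw)
  m <- stringr::str_match(
    raw, "^([A-Za-z][A-Za-z0-9+.-]*)://([^/:?#]+)(:([0-9]+))?([^?#]*)(\\?[^#]*)?(#.*)?$"
  )
  if (is.na(m[1, 1])) return(rejected("unparseable"))
  scheme <- tolower(m[1, 2])
  if (!scheme %in% c("http", "https")) return(rejected("scheme"))
  host <- tolower(m[1, 3])
  port <- m[1, 5]
  path <- m[1, 6]
  query <- m[1, 7]
  if (is.na(query)) query <- ""
  keep_port <- !is.na(port) &&
    !(scheme == "http" && port == "80") &&
    !(scheme == "https" && port == "443")
  path <- resolve_dot_segments(if (is.na(path) || !nzchar(path)) "/" else path)
  depth <- length(strsplit(path, "/", fixed = TRUE)[[1]]) - 1L
  if (depth > max_path_depth) return(rejected("path_depth"))
  url <- paste0(scheme, "://", host,
                if (keep_port) paste0(":", port) else "", path, query)
  if (nchar(url) > max_length) return(rejected("length"))
  tld <- host_cctld(host)
  if (!is.null(allowed_tlds) && !(tld %in% allowed_tlds)) {
    return(rejected("tld"))
  }
  list(url = url, host = host, cctld = tld, ok = TRUE, reason = NA_character_)
}

#' Normalize URLs and enforce crawl-scope rules
#'
#' Applies RFC 3986 normalization — scheme and host lowercased, default
#' ports dropped, dot-segments resolved, fragment removed — and rejects URLs
#' outside the crawl scope: non-HTTP schemes, hostnames whose ccTLD is not
#' in `allowed_tlds`, over-long URLs and overly deep paths (the latter two
#' are spider-trap defenses).
#'
#' @param raw Character vector of raw URLs (absolute).
#' @param allowed_tlds `NULL` (no restriction) or a subset of
#'   `c(".de", ".at", ".ch", "other")`.
#' @param max_length Maximum URL length in characters.
#' @param max_path_depth Maximum number of path segments.
#' @return Tibble with columns `raw`, `url`, `host`, `cctld`, `ok`,
#'   `reason`; `url` is `NA` for rejected rows.
#' @export
#' @examples
#' normalize_url("HTTP://WWW.Example.DE:80/a/../b#x")
normalize_url <- function(raw, allowed_tlds = NULL, max_length = 2048L,
                          max_path_depth = 20L) {
  rows <- lapply(raw, normalize_url1, allowed_tlds = allowed_tlds,
                 max_length = max_length, max_path_depth = max_path_depth)
  tibble::tibble(
    raw = raw,
    url = vapply(rows, `[[`, character(1), "url"),
    host = vapply(rows, `[[`, character(1), "host"),
    cctld = vapply(rows, `[[`, character(1), "cctld"),
    ok = vapply(rows, `[[`, logical(1), "ok"),
    reason = vapply(rows, `[[`, character(1), "reason")
  )
}
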