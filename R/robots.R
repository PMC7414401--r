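#' Parse robot-exclusion rules
#'
#' Parses a robots.txt body into per-agent rule groups. Unparseable lines
#' and comments are ignored, per the robustness requirement of the
#' exclusion protocol.
#'
#' @param text robots.txt content as a single string or character vector of
#'   lines; `NULL`/`NA` means no rules.
#' @return Tibble with columns `agent`, `directive` (`"allow"`/`"disallow"`)
#'   and `path`.
#' @export
parse_robots <- function(text) {
  empty <- tibble::tibble(agent = character(), directive = character(),
                          path = character())
  if (is.null(text) || length(text) == 0 || all(is.na(text))) return(empty)
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  lines <- sub("#.*$", "", lines)
  m <- stringr::str_match(lines, "^\\s*([A-Za-z-]+)\\s*:\\s*(.*?)\\s*$")
  agents <- character(0)
  rows <- list()
  current_agents <- character(0)
  in_group_body <- FALSE
  for (i in seq_along(lines)) {
    if (is.na(m[i, 1])) next
    field <- tolower(m[i, 2])
    value <- m[i, 3]
    if (field == "user-agent") {
      if (in_group_body) current_agents <- character(0)
      current_agents <- c(current_agents, tolower(value))
      in_group_body <- FALSE
    } else if (field %in% c("allow", "disallow")) {
      in_group_body <- TRUE
      if (length(current_agents) == 0) next
      for (a in current_agents) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          agent = a, directive = field, path = value
        )
      }
    }
  }
  if (length(rows) == 0) return(empty)
  dplyr::bind_rows(rows)
}

#' Decide whether a URL may be fetched under robot-exclusion rules
#'
#' Standard semantics: the most specific matching user-agent group applies
#' (a group naming the agent overrides the `*` wildcard group); within the
#' group the longest matching path rule wins, with `allow` beating
#' `disallow` on ties. Missing or empty rules, or an empty `Disallow:`
#' value, permit the fetch.
#'
#' @param rules robots.txt content (string), or `NULL`/`NA` for none.
#' @param agent The crawler's user-agent name.
#' @param url URL (or path) being considered.
#' @return `TRUE` if fetching is allowed.
#' @export
#' @examples
#' robots_allowed("User-agent: *\nDisallow: /private", "bot",
#'                "http://a.de/private/x")
robots_allowed <- function(rules, agent, url) {
  parsed <- if (is.data.frame(rules)) rules else parse_robots(rules)
  if (nrow(parsed) == 0) return(TRUE)
  path <- sub("^https?://[^/]+", "", url)
  if (!nzchar(path)) path <- "/"
  agent <- tolower(agent)
  # group selection: longest agent token contained in our agent name wins;
  # wildcard only if no named group matches
  named <- parsed[parsed$agent != "*", ]
  match_len <- if (nrow(named) > 0) {
    vapply(named$agent, function(a) {
      if (stringr::str_detect(agent, stringr::fixed(a))) nchar(a) else -1L
    }, integer(1))
  } else integer(0)
  group <- if (length(match_len) > 0 && max(match_len) >= 0) {
    named[named$agent %in% named$agent[match_len == max(match_len)], ]
  } else {
    parsed[parsed$agent == "*", ]
  }
  if (nrow(group) == 0) return(TRUE)
  applies <- nzchar(group$path) & startsWith(path, group$path)
  if (!any(applies)) return(TRUE)
  hit <- group[applies, ]
  best <- nchar(hit$path) == max(nchar(hit$path))
  any(hit$directive[best] == "allow") || all(hit$directive[best] != "disallow")
}
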