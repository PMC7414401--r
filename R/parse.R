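#' Parse a web page: links, visible text, boilerplate removal
#'
#' Tolerant HTML parsing (libxml2 recovery mode): never raises on broken or
#' invalid markup. Hyperlinks and anchor texts are extracted from the full
#' document; elements carrying a configured boilerplate class (and their
#' subtrees) are then removed before the visible text is assembled, so page
#' classification sees content only. A page whose markup is not well-formed
#' gets `malformed = TRUE`.
#'
#' @param html Markup string (possibly broken).
#' @param base_url Base URL for resolving relative links.
#' @param boilerplate_classes CSS classes marking boilerplate containers.
#' @return A list of class `parsed_page` with `url`, `text`, `links`
#'   (tibble `url`, `anchor`, `ok`, `reason` — normalized, no TLD
#'   restriction) and `malformed`.
#' @export
parse_page <- function(html, base_url,
                       boilerplate_classes = "boilerplate") {
  empty <- function(malformed) {
    structure(list(url = base_url, text = "",
                   links = tibble::tibble(url = character(),
                                          anchor = character(),
                                          ok = logical(),
                                          reason = character()),
                   malformed = malformed),
              class = "parsed_page")
  }
  if (is.null(html) || length(html) != 1L || is.na(html) || !nzchar(html)) {
    return(empty(malformed = FALSE))
  }
  malformed <- inherits(try(xml2::read_xml(html), silent = TRUE), "try-error")
  doc <- try(xml2::read_html(html), silent = TRUE)
  if (inherits(doc, "try-error")) return(empty(malformed = TRUE))

  anchors <- xml2::xml_find_all(doc, ".//a[@href]")
  hrefs <- xml2::xml_attr(anchors, "href")
  texts <- stringr::str_squish(xml2::xml_text(anchors))
  abs <- vapply(hrefs, function(h) {
    out <- try(xml2::url_absolute(h, base_url), silent = TRUE)
    if (inherits(out, "try-error") || is.na(out)) h else out
  }, character(1), USE.NAMES = FALSE)
  norm <- normalize_url(abs)
  links <- tibble::tibble(url = norm$url, anchor = texts,
                          ok = norm$ok, reason = norm$reason)

  for (cls in boilerplate_classes) {
    xpath <- sprintf(
      ".//*[contains(concat(' ', normalize-space(@class), ' '), ' %s ')]", cls
    )
    xml2::xml_remove(xml2::xml_find_all(doc, xpath))
  }
  body <- xml2::xml_find_first(doc, "//body")
  if (inherits(body, "xml_missing")) body <- doc
  text <- stringr::str_squish(xml2::xml_text(body))

  structure(list(url = base_url, text = text, links = links,
                 malformed = malformed),
            class = "parsed_page")
}

#' @export
print.parsed_page <- function(x, ...) {
  cat("<parsed_page> ", x$url, "\n  ", nrow(x$links), " links, ",
      nchar(x$text), " chars of text",
      if (x$malformed) " (malformed markup)" else "", "\n", sep = "")
  invisible(x)
}
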