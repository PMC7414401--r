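#' Text preprocessing configuration
#'
#' Controls tokenization-stage normalization: case folding, stop-word removal
#' and stemming. The stemmer is pluggable — either a named character vector
#' mapping tokens to stems (unlisted tokens pass through) or a function
#' `character -> character`. The default stemmer is the identity, suitable
#' for synthetic corpora; a language-specific stemmer (e.g. for German) can
#' be supplied without touching the rest of the pipeline.
#'
#' @param stop_words Character vector of stop words (compared after case
#'   folding when `lowercase` is on).
#' @param stemmer `NULL` (identity), a named character vector, or a function.
#' @param lowercase Apply case folding first (default `TRUE`).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(stop_words = character(),
                              stemmer = NULL,
                              lowercase = TRUE) {
  if (lowercase) stop_words <- tolower(stop_words)
  if (!is.null(stemmer) && !is.function(stemmer) &&
      !(is.character(stemmer) && !is.null(names(stemmer)))) {
    stop_input("stemmer must be NULL, a named character vector, or a function")
  }
  structure(list(stop_words = stop_words, stemmer = stemmer,
                 lowercase = lowercase),
            class = "preprocess_config")
}

apply_stemmer <- function(tokens, stemmer) {
  if (is.null(stemmer) || length(tokens) == 0) return(tokens)
  if (is.function(stemmer)) return(stemmer(tokens))
  hit <- tokens %in% names(stemmer)
  tokens[hit] <- unname(stemmer[tokens[hit]])
  tokens
}

#' Tokenize and normalize raw text
#'
#' Splits text into word fragments on non-alphanumeric boundaries, applies
#' case folding, removes stop words and maps each remaining token to its
#' stem. Token order is preserved. Empty input yields an empty vector.
#'
#' @param text Character vector of raw texts.
#' @param config A [preprocess_config()].
#' @return For a single input string, a character vector of tokens; for a
#'   vector input, a list of token vectors.
#' @export
#' @examples
#' preprocess_text("The AND the", preprocess_config(stop_words = c("the", "and")))
preprocess_text <- function(text, config = preprocess_config()) {
  out <- lapply(text, function(x) {
    if (is.na(x) || !nzchar(x)) return(character())
    if (config$lowercase) x <- tolower(x)
    tok <- stringr::str_split_1(x, "[^\\p{L}\\p{N}]+")
    tok <- tok[nzchar(tok)]
    tok <- tok[!(tok %in% config$stop_words)]
    apply_stemmer(tok, config$stemmer)
  })
  if (length(text) == 1L) out[[1]] else out
}

#' Strip markup and boilerplate before classification
#'
#' Convenience wrapper: removes configurable boilerplate containers and all
#' HTML tags from a markup string, returning plain visible text. Tolerant of
#' broken markup.
#'
#' @param html Markup string.
#' @param boilerplate_classes CSS classes whose elements are dropped.
#' @return A plain-text string.
#' @export
strip_markup <- function(html, boilerplate_classes = "boilerplate") {
  parse_page(html, base_url = "http://localhost/",
             boilerplate_classes = boilerplate_classes)$text
}
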