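#' Configuration for the synthetic two-class corpus generator
#'
#' Describes a labeled document collection with a health-related class `H` and
#' a general-language class `G`. Each class owns a vocabulary; a fraction of
#' tokens in every document is drawn from a shared (overlapping) vocabulary so
#' that class separability can be tuned continuously from perfectly separable
#' (`overlap_fraction = 0`) to indistinguishable (`overlap_fraction = 1`).
#'
#' @param n_docs_per_class Number of documents generated for each class.
#' @param vocab_size_topic Size of the topic-specific (`H`) vocabulary.
#' @param vocab_size_general Size of the general (`G`) vocabulary.
#' @param overlap_fraction Probability that a token is drawn from the shared
#'   vocabulary rather than the class-specific one. `0` gives disjoint
#'   supports, `1` makes the two class token distributions identical.
#' @param doc_length_mean Mean document length in tokens; lengths are
#'   Poisson-distributed with a minimum of one token.
#' @param rng_seed Integer seed; identical configurations generate
#'   byte-identical corpora.
#'
#' @return A list of class `corpus_config`.
#' @export
#' @examples
#' cfg <- corpus_config(n_docs_per_class = 10, rng_seed = 42)
#' generate_corpus(cfg)
corpus_config <- function(n_docs_per_class = 200,
                          vocab_size_topic = 150,
                          vocab_size_general = 150,
                          overlap_fraction = 0.1,
                          doc_length_mean = 80,
                          rng_seed = 1L) {
  check_count(n_docs_per_class, "n_docs_per_class")
  check_count(vocab_size_topic, "vocab_size_topic")
  check_count(vocab_size_general, "vocab_size_general")
  check_fraction(overlap_fraction, "overlap_fraction")
  check_count(doc_length_mean, "doc_length_mean")
  structure(
    list(
      n_docs_per_class = as.integer(n_docs_per_class),
      vocab_size_topic = as.integer(vocab_size_topic),
      vocab_size_general = as.integer(vocab_size_general),
      overlap_fraction = overlap_fraction,
      doc_length_mean = as.integer(doc_length_mean),
      rng_seed = as.integer(rng_seed)
    ),
    class = "corpus_config"
  )
}

corpus_vocabularies <- function(config) {
  list(
    topic = sprintf("med%04d", seq_len(config$vocab_size_topic)),
    general = sprintf("gen%04d", seq_len(config$vocab_size_general)),
    shared = sprintf("com%04d",
                     seq_len(max(1L, min(config$vocab_size_topic,
                                         config$vocab_size_general))))
  )
}

#' Generate a labeled two-class synthetic corpus
#'
#' Draws balanced document sets for the classes `H` (topical) and `G`
#' (general). Tokens come from the class vocabulary or, with probability
#' `overlap_fraction`, from a shared vocabulary common to both classes.
#'
#' @param config A [corpus_config()].
#' @return A tibble with columns `id`, `class` (`"H"` or `"G"`) and `text`,
#'   containing exactly `n_docs_per_class` rows per class.
#' @export
generate_corpus <- function(config) {
  if (!inherits(config, "corpus_config")) {
    stop_input("`config` must be created by corpus_config()")
  }
  vocab <- corpus_vocabularies(config)
  with_rng(config$rng_seed, {
    n <- config$n_docs_per_class
    classes <- rep(c("H", "G"), each = n)
    texts <- vapply(seq_along(classes), function(i) {
      own <- if (classes[i] == "H") vocab$topic else vocab$general
      len <- max(1L, stats::rpois(1L, config$doc_length_mean))
      from_shared <- stats::runif(len) < config$overlap_fraction
      tok <- character(len)
      if (any(from_shared)) {
        tok[from_shared] <- sample(vocab$shared, sum(from_shared), replace = TRUE)
      }
      if (any(!from_shared)) {
        tok[!from_shared] <- sample(own, sum(!from_shared), replace = TRUE)
      }
      paste(tok, collapse = " ")
    }, character(1))
    tibble::tibble(
      id = sprintf("doc%05d", seq_along(classes)),
      class = classes,
      text = texts
    )
  })
}

#' Write / read a corpus as JSON lines
#'
#' One JSON object per line with fields `id`, `class`, `text`.
#'
#' @param corpus A corpus tibble as returned by [generate_corpus()].
#' @param path File path.
#' @return `write_corpus_jsonl()` returns `path` invisibly;
#'   `read_corpus_jsonl()` returns the corpus tibble.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  lines <- vapply(seq_len(nrow(corpus)), function(i) {
    jsonlite::toJSON(as.list(corpus[i, c("id", "class", "text")]),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_corpus_jsonl
#' @export
read_corpus_jsonl <- function(path) {
  rows <- lapply(readLines(path, warn = FALSE), jsonlite::fromJSON)
  tibble::tibble(
    id = vapply(rows, `[[`, character(1), "id"),
    class = vapply(rows, `[[`, character(1), "class"),
    text = vapply(rows, `[[`, character(1), "text")
  )
}
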