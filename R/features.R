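#' Binary entropy helpers (base 2, 0 log 0 := 0)
#' @noRd
entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Information gain of term presence for a two-class corpus
#'
#' Computes, per term, the reduction in class entropy obtained by observing
#' whether the term is present in a document:
#' `IG(t) = H(C) - [P(t) H(C | t) + P(!t) H(C | !t)]`, with base-2
#' logarithms and the convention `0 log 0 = 0`. Term occurrence is binary
#' (document presence), matching its use for feature selection.
#'
#' @param present_h,present_g Number of documents of class `H` / `G`
#'   containing the term (vectorized over terms).
#' @param total_h,total_g Total documents per class.
#' @return Numeric vector of information gain in bits.
#' @export
#' @examples
#' information_gain(10, 0, 10, 10) # perfect separator of balanced classes: 1
information_gain <- function(present_h, present_g, total_h, total_g) {
  if (any(c(total_h, total_g) <= 0)) {
    stop_input("class totals must be positive")
  }
  if (any(present_h < 0) || any(present_g < 0) ||
      any(present_h > total_h) || any(present_g > total_g)) {
    stop_input("inconsistent counts: need 0 <= presence <= class total")
  }
  n <- total_h + total_g
  h_c <- entropy_bits(c(total_h, total_g) / n)
  vapply(seq_along(present_h), function(i) {
    np <- present_h[i] + present_g[i]
    na <- n - np
    h_p <- if (np > 0) entropy_bits(c(present_h[i], present_g[i]) / np) else 0
    h_a <- if (na > 0) {
      entropy_bits(c(total_h - present_h[i], total_g - present_g[i]) / na)
    } else 0
    h_c - (np / n) * h_p - (na / n) * h_a
  }, numeric(1))
}

corpus_tokens <- function(corpus, config) {
  toks <- preprocess_text(corpus$text, config)
  if (!is.list(toks)) toks <- list(toks)
  toks
}

#' Select the top-k features by information gain
#'
#' Ranks every distinct stem in the corpus by the information gain of its
#' document presence and keeps the `k` best. Ties are broken
#' lexicographically (smaller term first) so selection is deterministic.
#'
#' @param corpus Corpus tibble with columns `class` (`"H"`/`"G"`) and `text`.
#' @param k Number of features to keep; capped at the vocabulary size.
#' @param config A [preprocess_config()].
#' @return A tibble of class `feature_set` with columns `term` and
#'   `ig_score`, ordered by descending gain.
#' @export
select_features <- function(corpus, k, config = preprocess_config()) {
  check_count(k, "k")
  if (nrow(corpus) == 0) stop_input("corpus is empty")
  toks <- corpus_tokens(corpus, config)
  uniq <- lapply(toks, unique)
  term <- unlist(uniq, use.names = FALSE)
  cls <- rep(corpus$class, lengths(uniq))
  tab <- table(term, factor(cls, levels = c("H", "G")))
  total_h <- sum(corpus$class == "H")
  total_g <- sum(corpus$class == "G")
  terms <- rownames(tab)
  ig <- information_gain(as.numeric(tab[, "H"]), as.numeric(tab[, "G"]),
                         total_h, total_g)
  ord <- order(-ig, terms)
  keep <- ord[seq_len(min(k, length(terms)))]
  out <- tibble::tibble(term = terms[keep], ig_score = ig[keep])
  class(out) <- c("feature_set", class(out))
  attr(out, "k") <- as.integer(k)
  attr(out, "preprocess") <- config
  out
}

#' Document-term count table
#'
#' @param corpus Corpus tibble.
#' @param terms Character vector restricting the vocabulary (optional).
#' @param config A [preprocess_config()].
#' @return Sparse document x term count matrix (`dgCMatrix`), rows in corpus
#'   order.
#' @export
term_counts <- function(corpus, terms = NULL, config = preprocess_config()) {
  toks <- corpus_tokens(corpus, config)
  if (is.null(terms)) {
    terms <- sort(unique(unlist(toks, use.names = FALSE)))
  }
  doc_i <- rep(seq_along(toks), lengths(toks))
  term_j <- match(unlist(toks, use.names = FALSE), terms)
  keep <- !is.na(term_j)
  m <- Matrix::sparseMatrix(
    i = doc_i[keep], j = term_j[keep], x = 1,
    dims = c(length(toks), length(terms)),
    dimnames = list(corpus$id %||% as.character(seq_along(toks)), terms)
  )
  methods::as(m, "CsparseMatrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' tfc term weighting (tf-idf with cosine normalization)
#'
#' Raw weight of term `t` in document `d` is `tf(t, d) * ln(N / df(t))`,
#' where `N` is the number of documents and `df` the document frequency;
#' each document vector is then scaled to unit Euclidean norm (all-zero
#' vectors stay zero). A term present in every document receives idf 0.
#'
#' @param counts Sparse or dense document x term count matrix (e.g. from
#'   [term_counts()]), or a tidy tibble with columns `doc`, `term`, `n`.
#' @param df Optional externally supplied document frequencies (named
#'   vector over the matrix's terms) and
#' @param n_docs corpus size to use for the idf — both default to the input
#'   matrix itself; a trained model supplies its training values here so
#'   unseen documents are weighted consistently.
#' @return Sparse matrix of the same shape with unit-norm rows.
#' @export
tfc_weight <- function(counts, df = NULL, n_docs = NULL) {
  if (is.data.frame(counts)) {
    terms <- sort(unique(counts$term))
    docs <- unique(counts$doc)
    counts <- Matrix::sparseMatrix(
      i = match(counts$doc, docs), j = match(counts$term, terms),
      x = counts$n, dims = c(length(docs), length(terms)),
      dimnames = list(docs, terms)
    )
  }
  counts <- methods::as(counts, "CsparseMatrix")
  if (is.null(n_docs)) n_docs <- nrow(counts)
  if (is.null(df)) {
    df <- Matrix::colSums(counts > 0)
  } else {
    df <- df[colnames(counts)]
  }
  idf <- ifelse(df > 0, log(n_docs / df), 0)
  w <- counts %*% Matrix::Diagonal(x = idf)
  norms <- sqrt(Matrix::rowSums(w^2))
  norms[norms == 0] <- 1
  out <- Matrix::Diagonal(x = 1 / norms) %*% w
  dimnames(out) <- dimnames(counts)
  methods::as(out, "CsparseMatrix")
}
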