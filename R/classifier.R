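#' Balance classes and split into training and test sets
#'
#' Down-samples the majority class to the minority size (the real-world class
#' distribution being unknown, training on balanced classes avoids a skewed
#' decision threshold), then splits each class with the same fraction so both
#' partitions stay exactly balanced.
#'
#' @param corpus Corpus tibble with columns `class` and `text`.
#' @param train_fraction Fraction of each class used for training
#'   (default 0.8, i.e. an 80:20 split).
#' @param seed Integer seed; identical seeds give identical splits.
#' @return A list with tibbles `train` and `test`; the two are disjoint.
#' @export
split_and_balance <- function(corpus, train_fraction = 0.8, seed = 1L) {
  check_fraction(train_fraction, "train_fraction")
  n_by <- table(factor(corpus$class, levels = c("H", "G")))
  if (any(n_by < 5)) {
    stop_input("each class needs at least 5 documents, got H=", n_by["H"],
               " G=", n_by["G"])
  }
  n_min <- min(n_by)
  with_rng(seed, {
    parts <- lapply(c("H", "G"), function(cl) {
      idx <- which(corpus$class == cl)
      idx <- sample(idx, n_min)          # down-sample majority, shuffle both
      n_train <- floor(train_fraction * n_min)
      list(train = idx[seq_len(n_train)],
           test = idx[setdiff(seq_len(n_min), seq_len(n_train))])
    })
    list(
      train = corpus[c(parts[[1]]$train, parts[[2]]$train), ],
      test = corpus[c(parts[[1]]$test, parts[[2]]$test), ]
    )
  })
}

#' Default hyperparameter grid for the RBF-kernel SVM
#'
#' The exponential grid recommended by the LIBSVM authors:
#' `C = 2^(-5), 2^(-3), ..., 2^15` and `gamma = 2^(-15), 2^(-13), ..., 2^3`.
#'
#' @return Tibble with columns `cost` and `gamma`.
#' @export
default_svm_grid <- function() {
  tidyr::expand_grid(cost = 2^seq(-5, 15, by = 2),
                     gamma = 2^seq(-15, 3, by = 2))
}

#' A small grid for quick experiments and examples
#' @return Tibble with columns `cost` and `gamma`.
#' @export
small_svm_grid <- function() {
  tidyr::expand_grid(cost = 2^c(-1, 3, 7), gamma = 2^c(-7, -3, 1))
}

stratified_folds <- function(classes, folds) {
  fold <- integer(length(classes))
  for (cl in unique(classes)) {
    idx <- sample(which(classes == cl))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Train the relevance classifier by cross-validated grid search
#'
#' Full training pipeline for the page-relevance SVM: preprocess the training
#' corpus, select the top-`k` stems by information gain, weight documents
#' with tfc (tf-idf, cosine-normalized), then choose `(C, gamma)` for an
#' RBF-kernel SVM by stratified k-fold cross-validated accuracy and refit on
#' the full training set with sigmoid probability calibration. Ties in CV
#' accuracy are broken by smaller `C`, then smaller `gamma`.
#'
#' @param train Training corpus tibble (`class`, `text`).
#' @param grid Tibble of `cost`/`gamma` candidates; see [default_svm_grid()].
#' @param folds Number of cross-validation folds (default 10).
#' @param seed Integer seed controlling fold assignment and the SVM's
#'   internal probability calibration.
#' @param k Number of features kept by information gain.
#' @param preprocess A [preprocess_config()].
#' @return An object of class `relevance_model`.
#' @export
train_grid_cv <- function(train, grid = default_svm_grid(), folds = 10L,
                          seed = 1L, k = 200L,
                          preprocess = preprocess_config()) {
  if (nrow(grid) == 0) stop_input("hyperparameter grid is empty")
  n_by <- table(factor(train$class, levels = c("H", "G")))
  if (any(n_by < folds)) {
    stop_input("need at least `folds` documents per class; got H=",
               n_by["H"], " G=", n_by["G"], " for ", folds, " folds")
  }
  feats <- select_features(train, k = k, config = preprocess)
  counts <- term_counts(train, terms = feats$term, config = preprocess)
  df <- Matrix::colSums(counts > 0)
  n_docs <- nrow(counts)
  x <- as.matrix(tfc_weight(counts, df = df, n_docs = n_docs))
  y <- factor(train$class, levels = c("H", "G"))

  cv_acc <- with_rng(substream_seed(seed, "folds"), {
    fold <- stratified_folds(train$class, folds)
    vapply(seq_len(nrow(grid)), function(g) {
      correct <- 0L
      for (f in seq_len(folds)) {
        hold <- fold == f
        fit <- e1071::svm(x[!hold, , drop = FALSE], y[!hold],
                          kernel = "radial", cost = grid$cost[g],
                          gamma = grid$gamma[g], scale = FALSE)
        pred <- stats::predict(fit, x[hold, , drop = FALSE])
        correct <- correct + sum(pred == y[hold])
      }
      correct / length(y)
    }, numeric(1))
  })

  ord <- order(-cv_acc, grid$cost, grid$gamma)
  best <- ord[1]
  final <- with_rng(substream_seed(seed, "final-fit"), {
    e1071::svm(x, y, kernel = "radial", cost = grid$cost[best],
               gamma = grid$gamma[best], scale = FALSE, probability = TRUE)
  })

  structure(
    list(
      svm_fit = final,
      feature_set = feats,
      df = df,
      n_docs = n_docs,
      preprocess = preprocess,
      grid_results = tibble::tibble(cost = grid$cost, gamma = grid$gamma,
                                    cv_accuracy = cv_acc),
      best = list(cost = grid$cost[best], gamma = grid$gamma[best],
                  cv_accuracy = cv_acc[best]),
      folds = as.integer(folds),
      seed = as.integer(seed)
    ),
    class = "relevance_model"
  )
}

#' @export
print.relevance_model <- function(x, ...) {
  cat("<relevance_model> RBF SVM, ", nrow(x$feature_set), " features\n",
      "  best C = ", format(x$best$cost), ", gamma = ", format(x$best$gamma),
      " (CV accuracy ", round(x$best$cv_accuracy, 4), ", ",
      x$folds, "-fold)\n", sep = "")
  invisible(x)
}

model_vectors <- function(model, texts) {
  corpus <- tibble::tibble(id = as.character(seq_along(texts)), text = texts)
  counts <- term_counts(corpus, terms = model$feature_set$term,
                        config = model$preprocess)
  as.matrix(tfc_weight(counts, df = model$df, n_docs = model$n_docs))
}

#' Classify texts with a trained relevance model
#'
#' Applies the model's own preprocessing, feature set and training-corpus
#' idf to new raw texts and returns the calibrated probability of the
#' health-related class `H`. The label is `H` iff that probability is at
#' least 0.5. Deterministic: identical text gives identical output.
#'
#' @param model A `relevance_model` from [train_grid_cv()].
#' @param text Character vector of raw texts (may be empty strings).
#' @return Tibble with one row per input: `label` (`"H"`/`"G"`) and
#'   `prob_h`.
#' @export
classify <- function(model, text) {
  if (!inherits(model, "relevance_model")) {
    stop_input("`model` must be a relevance_model")
  }
  if (length(text) == 0) {
    return(tibble::tibble(label = character(), prob_h = numeric()))
  }
  x <- model_vectors(model, text)
  pred <- stats::predict(model$svm_fit, x, probability = TRUE)
  prob_h <- unname(attr(pred, "probabilities")[, "H"])
  tibble::tibble(label = ifelse(prob_h >= 0.5, "H", "G"),
                 prob_h = prob_h)
}

#' Confusion matrix and derived metrics
#'
#' `confusion_matrix()` builds the 2x2 table (positive class `H`; rows are
#' predictions, columns actual classes). `metrics_from_confusion()` computes
#' accuracy `(tp+tn)/total`, precision `tp/(tp+fp)` and recall `tp/(tp+fn)`
#' in exact arithmetic; a metric with a zero denominator is reported as `NA`
#' rather than 0.
#'
#' @param predicted,actual Character vectors of `"H"`/`"G"` labels.
#' @return `confusion_matrix()`: a list of class `confusion_matrix` with
#'   counts `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_matrix <- function(predicted, actual) {
  structure(
    list(tp = sum(predicted == "H" & actual == "H"),
         fp = sum(predicted == "H" & actual == "G"),
         fn = sum(predicted == "G" & actual == "H"),
         tn = sum(predicted == "G" & actual == "G")),
    class = "confusion_matrix"
  )
}

#' @rdname confusion_matrix
#' @param m A `confusion_matrix`, or `tp` as a count when the four counts are
#'   given directly.
#' @param fp,fn,tn Counts (used when `m` is numeric).
#' @return `metrics_from_confusion()`: tibble with columns `accuracy`,
#'   `precision`, `recall`.
#' @export
#' @examples
#' metrics_from_confusion(8182, 575, 522, 8235)
metrics_from_confusion <- function(m, fp = NULL, fn = NULL, tn = NULL) {
  if (is.numeric(m)) {
    m <- structure(list(tp = m, fp = fp, fn = fn, tn = tn),
                   class = "confusion_matrix")
  }
  counts <- c(m$tp, m$fp, m$fn, m$tn)
  if (any(counts < 0)) stop_input("confusion counts must be nonnegative")
  total <- sum(counts)
  if (total == 0) stop_input("confusion matrix is all zero")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  tibble::tibble(
    accuracy = (m$tp + m$tn) / total,
    precision = ratio(m$tp, m$tp + m$fp),
    recall = ratio(m$tp, m$tp + m$fn)
  )
}

#' Evaluate a model on a labeled corpus
#'
#' @param model A `relevance_model`.
#' @param corpus Labeled corpus tibble (`class`, `text`).
#' @return Tibble with the confusion counts and accuracy/precision/recall.
#' @export
evaluate_model <- function(model, corpus) {
  pred <- classify(model, corpus$text)
  cm <- confusion_matrix(pred$label, corpus$class)
  dplyr::bind_cols(tibble::as_tibble(unclass(cm)), metrics_from_confusion(cm))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the cross-validation surface of a relevance model
#' @param x A `relevance_model`.
#' @param ... Unused.
#' @return Tibble of `cost`, `gamma`, `cv_accuracy` rows.
#' @export
tidy.relevance_model <- function(x, ...) {
  x$grid_results
}

#' One-row summary of a relevance model
#' @param x A `relevance_model`.
#' @param ... Unused.
#' @return Tibble with the selected hyperparameters, CV accuracy, feature
#'   count and fold count.
#' @export
glance.relevance_model <- function(x, ...) {
  tibble::tibble(cost = x$best$cost, gamma = x$best$gamma,
                 cv_accuracy = x$best$cv_accuracy,
                 n_features = nrow(x$feature_set),
                 n_train = x$n_docs, folds = x$folds)
}
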