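test_that("balanced 80:20 split arithmetic is exact", {
  corpus <- tibble::tibble(
    id = as.character(1:200),
    class = rep(c("H", "G"), each = 100),
    text = "x"
  )
  split <- split_and_balance(corpus, seed = 1)
  expect_equal(nrow(split$train), 160)
  expect_equal(nrow(split$test), 40)
  expect_equal(as.vector(table(split$train$class)), c(80, 80))
  expect_equal(as.vector(table(split$test$class)), c(20, 20))
  expect_length(intersect(split$train$id, split$test$id), 0)
  # same seed, same split
  expect_identical(split_and_balance(corpus, seed = 1), split)
})

test_that("a corpus of 87,562 balanced documents splits 70,048 / 17,514", {
  n <- 87562 / 2
  corpus <- tibble::tibble(id = as.character(seq_len(2 * n)),
                           class = rep(c("H", "G"), each = n), text = "x")
  split <- split_and_balance(corpus, seed = 3)
  expect_equal(nrow(split$train), 70048)
  expect_equal(nrow(split$test), 17514)
})

test_that("majority class is down-sampled before splitting", {
  corpus <- tibble::tibble(id = as.character(1:30),
                           class = c(rep("H", 10), rep("G", 20)), text = "x")
  split <- split_and_balance(corpus, seed = 1)
  expect_equal(as.vector(table(split$train$class)), c(8, 8))
  expect_equal(as.vector(table(split$test$class)), c(2, 2))
  expect_error(split_and_balance(corpus[1:12, ]), "at least 5")
})

test_that("grid search selects the better hyperparameters", {
  corpus <- generate_corpus(corpus_config(n_docs_per_class = 60,
                                          overlap_fraction = 0.05,
                                          rng_seed = 31))
  # gamma = 1e4 drastically overfits an RBF kernel; a sane point must win
  grid <- tibble::tibble(cost = c(1, 1), gamma = c(0.1, 1e4))
  model <- train_grid_cv(corpus, grid = grid, folds = 5, seed = 7, k = 80)
  expect_equal(model$best$gamma, 0.1)
  expect_gt(
    model$grid_results$cv_accuracy[model$grid_results$gamma == 0.1],
    model$grid_results$cv_accuracy[model$grid_results$gamma == 1e4]
  )
  # a one-point grid is selected trivially
  one <- train_grid_cv(corpus, grid = tibble::tibble(cost = 2, gamma = 0.1),
                       folds = 5, seed = 7, k = 80)
  expect_equal(one$best$cost, 2)
  expect_error(train_grid_cv(corpus, grid = tibble::tibble()), "grid")
})

test_that("separable data reaches CV accuracy 1 and ties prefer smaller C", {
  corpus <- generate_corpus(corpus_config(n_docs_per_class = 40,
                                          overlap_fraction = 0,
                                          rng_seed = 17))
  grid <- tibble::tibble(cost = c(8, 2), gamma = c(0.1, 0.1))
  model <- train_grid_cv(corpus, grid = grid, folds = 5, seed = 5, k = 80)
  expect_equal(max(model$grid_results$cv_accuracy), 1)
  # both points hit accuracy 1; tie broken by smaller C
  expect_equal(model$best$cost, 2)
})

test_that("classification is deterministic and separates training classes", {
  model <- test_model()
  h_text <- test_doc("H"); g_text <- test_doc("G")
  out <- classify(model, c(h_text, g_text))
  expect_equal(out$label, c("H", "G"))
  expect_gt(out$prob_h[1], 0.5)
  expect_lt(out$prob_h[2], 0.5)
  expect_identical(classify(model, h_text), classify(model, h_text))
  # empty text yields a valid probability
  empty <- classify(model, "")
  expect_true(empty$prob_h >= 0 && empty$prob_h <= 1)
})

test_that("held-out probability distribution is bimodal for disjoint vocab", {
  corpus <- generate_corpus(corpus_config(n_docs_per_class = 80,
                                          overlap_fraction = 0,
                                          rng_seed = 53))
  split <- split_and_balance(corpus, seed = 2)
  model <- train_grid_cv(split$train,
                         grid = tibble::tibble(cost = 8, gamma = 0.125),
                         folds = 5, seed = 2, k = 100)
  probs <- classify(model, split$test$text)$prob_h
  expect_gt(mean(probs < 0.2 | probs > 0.8), 0.9)
})

test_that("confusion metrics use exact ratios and signal undefined cases", {
  m <- metrics_from_confusion(8182, 575, 522, 8235)
  expect_equal(round(m$accuracy, 3), 0.937)
  expect_equal(round(m$precision, 3), 0.934)
  expect_equal(round(m$recall, 3), 0.940)
  expect_equal(m$accuracy, 16417 / 17514, tolerance = 1e-15)

  m2 <- metrics_from_confusion(181, 11, 2, 190)
  expect_equal(round(m2$accuracy, 3), 0.966)
  expect_equal(round(m2$recall, 3), 0.989)

  perfect <- metrics_from_confusion(5, 0, 0, 7)
  expect_equal(unlist(perfect), c(accuracy = 1, precision = 1, recall = 1))

  # nothing predicted positive: precision undefined, not zero
  none <- metrics_from_confusion(0, 0, 3, 7)
  expect_true(is.na(none$precision))
  expect_equal(none$accuracy, 0.7)
  expect_error(metrics_from_confusion(0, 0, 0, 0), "all zero")
  expect_error(metrics_from_confusion(-1, 0, 0, 1), "nonnegative")
})

test_that("tidy and glance expose the CV surface and chosen model", {
  model <- test_model()
  td <- tidy(model)
  expect_true(all(c("cost", "gamma", "cv_accuracy") %in% names(td)))
  gl <- glance(model)
  expect_equal(gl$n_features, nrow(model$feature_set))
  expect_equal(gl$cv_accuracy, max(td$cv_accuracy))
})
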