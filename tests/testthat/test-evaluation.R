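test_that("confusion counts follow the score-at-zero decision rule", {
  expect_equal(confusion_counts(c(1, -1, 1, -1), c(1, -1, -1, 1)),
               c(TP = 1L, TN = 1L, FP = 1L, FN = 1L))
  expect_equal(confusion_counts(c(2, -3), c(1, -1)),
               c(TP = 1L, TN = 1L, FP = 0L, FN = 0L))
  # a score of exactly zero predicts non-interaction
  expect_equal(confusion_counts(0, 1), c(TP = 0L, TN = 0L, FP = 0L, FN = 1L))
  expect_equal(confusion_counts(0, -1), c(TP = 0L, TN = 1L, FP = 0L, FN = 0L))
  expect_error(confusion_counts(numeric(0), numeric(0)), "no scores")
})

test_that("sensitivity, specificity and accuracy follow their definitions", {
  expect_equal(
    classification_metrics(c(TP = 8, FN = 2, TN = 0, FP = 0))[["sensitivity"]],
    0.8)
  expect_equal(
    classification_metrics(c(TN = 3, FP = 1, TP = 0, FN = 0))[["specificity"]],
    0.75)
  expect_equal(
    classification_metrics(c(TP = 5, TN = 5, FP = 0, FN = 0))[["accuracy"]], 1)
  # zero denominators are undefined, never silently zero
  m <- classification_metrics(c(TP = 0, FN = 0, TN = 4, FP = 1))
  expect_true(is.na(m[["sensitivity"]]))
  expect_false(is.na(m[["specificity"]]))
  # accuracy = (SE * P + SP * N) / (P + N), exactly
  set.seed(8)
  for (i in 1:20) {
    counts <- c(TP = sample(1:30, 1), FN = sample(1:30, 1),
                TN = sample(1:30, 1), FP = sample(1:30, 1))
    m <- classification_metrics(counts)
    P <- counts[["TP"]] + counts[["FN"]]
    N <- counts[["TN"]] + counts[["FP"]]
    expect_equal(m[["accuracy"]],
                 (m[["sensitivity"]] * P + m[["specificity"]] * N) / (P + N))
  }
})

test_that("AUC is the tie-aware rank statistic", {
  labels <- c(1, 1, -1, -1)
  expect_equal(auc_score(labels, labels), 1)   # perfect prediction
  expect_equal(auc_score(-labels, labels), 0)  # inverted prediction
  expect_equal(auc_score(rep(0.3, 4), labels), 0.5)  # constant scores
  expect_error(auc_score(c(1, 2), c(1, 1)), "both classes")
  set.seed(15)
  for (i in 1:15) {
    n <- sample(10:200, 1)
    labels <- c(rep(1, ceiling(n / 3)), rep(-1, n - ceiling(n / 3)))
    scores <- round(rnorm(n), 1)  # rounding forces ties
    expect_equal(auc_score(scores, labels), oracle_auc(scores, labels))
  }
})

test_that("AUC agrees with an established ROC implementation", {
  set.seed(27)
  labels <- sample(c(-1, 1), 150, replace = TRUE, prob = c(0.4, 0.6))
  scores <- rnorm(150) + 0.8 * (labels == 1)
  expect_equal(auc_score(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                              direction = "<"))))
})

test_that("stratified folds are seed-deterministic near-proportional partitions", {
  labels <- rep(c(1, -1), each = 50)
  f <- stratified_folds(labels, 10, seed = 42)
  expect_identical(f, stratified_folds(labels, 10, seed = 42))
  expect_false(identical(f, stratified_folds(labels, 10, seed = 43)))
  expect_equal(sort(unique(f)), 1:10)
  for (fold in 1:10) {  # 100 balanced pairs: exactly 5 + 5 per fold
    expect_equal(sum(f == fold & labels == 1), 5L)
    expect_equal(sum(f == fold & labels == -1), 5L)
  }
  # unbalanced, non-divisible classes: within 1 of proportionality
  labels2 <- c(rep(1, 13), rep(-1, 17))
  f2 <- stratified_folds(labels2, 10, seed = 7)
  expect_equal(tabulate(f2, 10), rep(3L, 10))
  for (cl in c(1, -1)) {
    per_fold <- vapply(1:10, function(k) sum(f2 == k & labels2 == cl), 0L)
    expect_lte(diff(range(per_fold)), 1L)
  }
  expect_error(stratified_folds(c(1, 1, -1), 2), "at least")
})

test_that("cross-validation partitions the pairs and never reuses test labels", {
  sim <- simulate_rpi_data(n_pairs = 60, seed = 33)
  cv <- rpi_cross_validate(sim$pairs, sim$proteins, sim$rnas, k = 3, l = 4,
                           n_folds = 5, seed = 2)
  expect_equal(sum(cv$folds$n_test), 60L)  # each pair tested exactly once
  expect_equal(sum(cv$folds$TP + cv$folds$TN + cv$folds$FP + cv$folds$FN), 60L)
  expect_equal(sort(unique(cv$fold_assignment)), 1:5)
  expect_true(all(cv$folds$lambda %in% rls_lambda_grid()))
  expect_gte(cv$mean[["auc"]], 0.9)  # separable planted-motif data
  # pooled metrics recompute from summed confusion counts
  pooled_acc <- (sum(cv$folds$TP) + sum(cv$folds$TN)) / 60
  expect_equal(cv$pooled[["accuracy"]], pooled_acc)
})

test_that("template-size grid search covers all cells and prefers the signal region", {
  sim <- simulate_rpi_data(n_pairs = 60, seed = 37)  # motifs of length 3 and 4
  gr <- rpi_grid_search(sim$pairs, sim$proteins, sim$rnas,
                        k_range = 1:3, l_range = 1:4, n_folds = 5, seed = 2)
  expect_equal(nrow(gr$cells), 12L)
  expect_false(any(is.na(gr$accuracy)))
  expect_lte(gr$best$k, 3)
  expect_lte(gr$best$l, 4)
  # a degenerate 1-cell grid reproduces plain cross-validation
  gr1 <- rpi_grid_search(sim$pairs, sim$proteins, sim$rnas,
                         k_range = 3, l_range = 4, n_folds = 5, seed = 2)
  cv <- rpi_cross_validate(sim$pairs, sim$proteins, sim$rnas, k = 3, l = 4,
                           n_folds = 5, seed = 2)
  expect_equal(gr1$cells$auc, unname(cv$mean[["auc"]]))
  expect_equal(gr1$cells$accuracy, unname(cv$mean[["accuracy"]]))
})
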