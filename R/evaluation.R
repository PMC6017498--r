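#' Confusion counts for scored pairs
#'
#' Applies the decision rule (score greater than \code{threshold}
#' predicts \eqn{+1}; a score at or below the threshold predicts
#' \eqn{-1}) and tabulates against the true labels.
#'
#' @param scores numeric prediction scores.
#' @param labels true labels in \eqn{\{-1, +1\}}.
#' @param threshold decision threshold (default 0).
#' @return Named integer vector \code{c(TP, TN, FP, FN)}.
#' @export
confusion_counts <- function(scores, labels, threshold = 0) {
  if (length(scores) == 0L) stopf("no scores to evaluate")
  if (length(scores) != length(labels))
    stopf("scores and labels differ in length")
  if (any(is.na(scores)) || any(is.na(labels)) || !all(labels %in% c(-1, 1)))
    stopf("labels must be -1/+1 and scores non-missing")
  pred <- ifelse(scores > threshold, 1, -1)
  c(TP = sum(pred == 1 & labels == 1),
    TN = sum(pred == -1 & labels == -1),
    FP = sum(pred == 1 & labels == -1),
    FN = sum(pred == -1 & labels == 1))
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' \eqn{SE = TP/(TP+FN)}, \eqn{SP = TN/(TN+FP)},
#' \eqn{ACC = (TP+TN)/(TP+TN+FP+FN)}. A metric whose denominator is
#' zero is reported as \code{NA} (undefined), never as 0.
#'
#' @param counts named vector with elements \code{TP, TN, FP, FN}, as
#'   returned by \code{\link{confusion_counts}}.
#' @return Named numeric vector \code{c(sensitivity, specificity,
#'   accuracy)}.
#' @export
classification_metrics <- function(counts) {
  stopifnot(all(c("TP", "TN", "FP", "FN") %in% names(counts)))
  tp <- counts[["TP"]]; tn <- counts[["TN"]]
  fp <- counts[["FP"]]; fn <- counts[["FN"]]
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  c(sensitivity = safe_div(tp, tp + fn),
    specificity = safe_div(tn, tn + fp),
    accuracy = safe_div(tp + tn, tp + tn + fp + fn))
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a random
#' positive pair outscores a random negative pair, with tied scores
#' counted as one half. 1 for perfect prediction, 0.5 for random
#' prediction.
#'
#' @inheritParams confusion_counts
#' @return AUC in \eqn{[0, 1]}.
#' @export
auc_score <- function(scores, labels) {
  if (length(scores) != length(labels) || any(is.na(scores)) ||
      any(is.na(labels)) || !all(labels %in% c(-1, 1)))
    stopf("scores and labels must be equal-length, non-missing, labels -1/+1")
  np <- sum(labels == 1)
  nn <- sum(labels == -1)
  if (np == 0L || nn == 0L)
    stopf("AUC requires both classes to be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Stratified fold assignment
#'
#' Partitions the indices into \code{n_folds} mutually exclusive folds
#' whose class proportions differ from the global proportions by at most
#' one example per class: within each class the indices are shuffled
#' with a seeded RNG and dealt round-robin, with the dealing origin
#' rotated between classes so that fold sizes also stay within one of
#' each other. Deterministic given \code{seed}; the caller's RNG state
#' is untouched.
#'
#' @param labels vector of class labels (\eqn{-1/+1}).
#' @param n_folds number of folds (default 10).
#' @param seed integer seed controlling the shuffle.
#' @return Integer vector of fold ids in \code{1..n_folds}, one per
#'   label.
#' @export
stratified_folds <- function(labels, n_folds = 10L, seed) {
  n_folds <- as.integer(n_folds)
  if (n_folds < 2L) stopf("need at least 2 folds")
  counts <- table(labels)
  if (any(counts < n_folds))
    stopf("each class needs at least %d examples for %d folds (smallest has %d)",
          n_folds, n_folds, min(counts))
  folds <- integer(length(labels))
  start <- 0L
  with_seed(seed, {
    for (cl in names(counts)) {
      idx <- sample(which(labels == cl))
      folds[idx] <- (start + seq_along(idx) - 1L) %% n_folds + 1L
      start <- (start + length(idx)) %% n_folds
    }
  })
  folds
}

# Stratified CV of the RLS classifier on a precomputed Gram matrix.
# Per fold: lambda is selected by leave-one-out on the training block
# only; metrics are computed on the held-out block. Test labels never
# influence selection.
cv_gram <- function(gram, labels, grid, n_folds, seed, scaling) {
  folds <- stratified_folds(labels, n_folds, seed)
  per_fold <- lapply(seq_len(n_folds), function(f) {
    tr <- folds != f
    sel <- loo_lambda(gram[tr, tr, drop = FALSE], labels[tr], grid, scaling)
    co <- rls_fit(gram[tr, tr, drop = FALSE], labels[tr], sel$lambda, scaling)
    scores <- drop(crossprod(gram[tr, !tr, drop = FALSE], co))
    conf <- confusion_counts(scores, labels[!tr])
    metrics <- classification_metrics(conf)
    data.frame(fold = f, n_test = sum(!tr), lambda = sel$lambda,
               TP = conf[["TP"]], TN = conf[["TN"]],
               FP = conf[["FP"]], FN = conf[["FN"]],
               sensitivity = metrics[["sensitivity"]],
               specificity = metrics[["specificity"]],
               accuracy = metrics[["accuracy"]],
               auc = auc_score(scores, labels[!tr]))
  })
  folds_df <- do.call(rbind, per_fold)
  pooled_conf <- c(TP = sum(folds_df$TP), TN = sum(folds_df$TN),
                   FP = sum(folds_df$FP), FN = sum(folds_df$FN))
  metric_cols <- c("sensitivity", "specificity", "accuracy", "auc")
  list(
    folds = folds_df,
    mean = colMeans(folds_df[metric_cols], na.rm = TRUE),
    sd = vapply(folds_df[metric_cols], stats::sd, numeric(1L), na.rm = TRUE),
    pooled = c(classification_metrics(pooled_conf)),
    fold_assignment = folds
  )
}

#' Stratified cross-validation of the interaction classifier
#'
#' Runs \code{n_folds}-fold stratified cross-validation of the full
#' training protocol: within each fold the ridge parameter is selected
#' by leave-one-out cross-validation on the training portion alone, the
#' model is refitted, and sensitivity, specificity, accuracy and AUC
#' are measured on the held-out portion. Held-out labels are never used
#' for parameter selection.
#'
#' @inheritParams rpirls
#' @param n_folds number of folds (default 10).
#' @param seed integer seed for the stratified fold shuffle.
#' @return An object of class \code{"rpi_cv"}: a list with \code{folds}
#'   (per-fold metrics and selected \eqn{\lambda}), \code{mean} and
#'   \code{sd} (across folds), \code{pooled} (metrics from summed
#'   confusion counts), the fold assignment, and the configuration
#'   (including \code{seed}).
#' @export
rpi_cross_validate <- function(pairs, proteins, rnas, k = NULL, l = NULL,
                               alphabet = c("full20", "reduced7g"),
                               grid = rls_lambda_grid(), n_folds = 10L,
                               seed = 1L, scaling = c("plain", "mean")) {
  alphabet <- match.arg(alphabet)
  scaling <- match.arg(scaling)
  k <- k %||% if (alphabet == "full20") 2L else 3L
  l <- l %||% if (alphabet == "full20") 5L else 4L
  check_template_sizes(k, l, alphabet)
  validate_pairs(pairs, need_labels = TRUE)
  G <- rpi_gram(pairs, proteins, rnas, k, l, alphabet)
  out <- cv_gram(G, as.numeric(pairs$label), grid, n_folds, seed, scaling)
  out$config <- list(k = k, l = l, alphabet = alphabet, n_folds = n_folds,
                     seed = seed, scaling = scaling)
  class(out) <- "rpi_cv"
  out
}

#' @export
print.rpi_cv <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("%d-fold stratified cross-validation (k = %d, l = %d, %s, seed %s)\n",
              cfg$n_folds, cfg$k, cfg$l, cfg$alphabet, cfg$seed))
  cat(sprintf("  mean AUC %.3f (sd %.3f), accuracy %.3f (sd %.3f)\n",
              x$mean[["auc"]], x$sd[["auc"]],
              x$mean[["accuracy"]], x$sd[["accuracy"]]))
  cat(sprintf("  mean SE %.3f, SP %.3f; pooled accuracy %.3f\n",
              x$mean[["sensitivity"]], x$mean[["specificity"]],
              x$pooled[["accuracy"]]))
  invisible(x)
}

#' Grid search over template sizes
#'
#' Runs the full cross-validation protocol for every combination of
#' protein template size \code{k_range} and RNA template size
#' \code{l_range}, reusing the per-sequence kernel matrices across
#' cells. The selected cell maximizes mean cross-validated accuracy;
#' ties are broken toward smaller \eqn{k + l} (then smaller \eqn{k}).
#'
#' @inheritParams rpi_cross_validate
#' @param k_range,l_range integer vectors of template sizes to explore.
#' @return An object of class \code{"rpi_grid"}: \code{cells} (one row
#'   per (k, l) with mean metrics across folds), \code{auc} and
#'   \code{accuracy} matrices (rows k, columns l), and \code{best}
#'   (the selected cell).
#' @export
rpi_grid_search <- function(pairs, proteins, rnas,
                            k_range = 1:4, l_range = 1:8,
                            alphabet = c("full20", "reduced7g"),
                            grid = rls_lambda_grid(), n_folds = 10L,
                            seed = 1L, scaling = c("plain", "mean")) {
  alphabet <- match.arg(alphabet)
  scaling <- match.arg(scaling)
  for (k in k_range) check_template_sizes(k, max(l_range), alphabet)
  validate_pairs(pairs, need_labels = TRUE)
  labels <- as.numeric(pairs$label)

  # one sequence-kernel matrix per template size, shared across cells
  KP <- lapply(k_range, function(k) {
    resp <- prepare_responses(pairs, proteins, rnas, k, 1L, alphabet)
    response_kernel_matrix(resp$protein)
  })
  KR <- lapply(l_range, function(l) {
    resp <- prepare_responses(pairs, proteins, rnas, 1L, l, alphabet)
    response_kernel_matrix(resp$rna)
  })
  names(KP) <- as.character(k_range)
  names(KR) <- as.character(l_range)

  cells <- expand.grid(k = k_range, l = l_range, KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    k <- cells$k[i]; l <- cells$l[i]
    G <- KR[[as.character(l)]][pairs$rna_id, pairs$rna_id, drop = FALSE] *
      KP[[as.character(k)]][pairs$protein_id, pairs$protein_id, drop = FALSE]
    cv <- cv_gram(G, labels, grid, n_folds, seed, scaling)
    data.frame(k = k, l = l,
               auc = cv$mean[["auc"]], accuracy = cv$mean[["accuracy"]],
               sensitivity = cv$mean[["sensitivity"]],
               specificity = cv$mean[["specificity"]])
  })
  cells_df <- do.call(rbind, res)
  acc_mat <- matrix(NA_real_, length(k_range), length(l_range),
                    dimnames = list(paste0("k=", k_range), paste0("l=", l_range)))
  auc_mat <- acc_mat
  for (i in seq_len(nrow(cells_df))) {
    ri <- match(cells_df$k[i], k_range); ci <- match(cells_df$l[i], l_range)
    acc_mat[ri, ci] <- cells_df$accuracy[i]
    auc_mat[ri, ci] <- cells_df$auc[i]
  }
  ord <- order(-cells_df$accuracy, cells_df$k + cells_df$l, cells_df$k)
  best <- cells_df[ord[1L], , drop = FALSE]
  structure(list(cells = cells_df, accuracy = acc_mat, auc = auc_mat,
                 best = best,
                 config = list(alphabet = alphabet, n_folds = n_folds,
                               seed = seed, scaling = scaling)),
            class = "rpi_grid")
}

#' @export
print.rpi_grid <- function(x, digits = 3L, ...) {
  cat(sprintf("Template-size grid search (%s, %d-fold CV, seed %s)\n",
              x$config$alphabet, x$config$n_folds, x$config$seed))
  cat("Mean cross-validated accuracy:\n")
  print(round(x$accuracy, digits))
  cat(sprintf("Best cell: k = %d, l = %d (accuracy %.3f, AUC %.3f)\n",
              x$best$k, x$best$l, x$best$accuracy, x$best$auc))
  invisible(x)
}
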