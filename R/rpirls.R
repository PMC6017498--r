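#' Fit an RNA-protein interaction classifier
#'
#' Fits a kernel regularized least squares classifier to labeled
#' RNA-protein pairs under the two-layer derived string kernel. Each
#' sequence is represented by its contiguous k-mer frequency profile
#' (protein template size \code{k}, RNA template size \code{l}),
#' sequence similarity is the correlation-normalized kernel of those
#' profiles, and pair similarity is the tensor product of the RNA and
#' protein kernels. With \code{lambda = NULL} the ridge parameter is
#' selected from \code{grid} by closed-form leave-one-out
#' cross-validation on the training pairs.
#'
#' Defaults are the operating points found best in the original
#' evaluation of this method: \code{k = 2, l = 5} for the full 20-letter
#' protein alphabet and \code{k = 3, l = 4} for the 7-group reduced
#' alphabet.
#'
#' @param pairs data.frame with columns \code{protein_id},
#'   \code{rna_id}, \code{label} (\eqn{-1/+1}).
#' @param proteins,rnas named character vectors of sequences resolving
#'   every id in \code{pairs}.
#' @param k protein template size (supported range 1--4 for
#'   \code{"full20"}, 1--6 for \code{"reduced7g"}).
#' @param l RNA template size (supported range 1--8).
#' @param alphabet protein representation, \code{"full20"} or
#'   \code{"reduced7g"}.
#' @param lambda positive ridge parameter, or \code{NULL} (default) for
#'   leave-one-out selection over \code{grid}.
#' @param grid candidate \eqn{\lambda} values for selection; see
#'   \code{\link{rls_lambda_grid}}.
#' @param scaling ridge convention, see \code{\link{rls_fit}}.
#' @param check_bounds set \code{FALSE} to allow template sizes outside
#'   the supported ranges (the template space grows as
#'   \eqn{|A|^k}, so large sizes are rarely useful).
#' @return An object of class \code{"rpirls"} with methods
#'   \code{print}, \code{summary}, \code{coef}, \code{fitted},
#'   \code{residuals}, \code{predict} and \code{plot}. Scores are real
#'   valued; the predicted class is \eqn{+1} when the score exceeds 0
#'   and \eqn{-1} otherwise.
#' @examples
#' sim <- simulate_rpi_data(n_pairs = 40, seed = 1)
#' fit <- rpirls(sim$pairs, sim$proteins, sim$rnas, k = 3, l = 4)
#' fit
#' head(predict(fit, sim$pairs, sim$proteins, sim$rnas))
#' @seealso \code{\link{rpi_cross_validate}}, \code{\link{rpi_grid_search}},
#'   \code{\link{simulate_rpi_data}}
#' @export
rpirls <- function(pairs, proteins, rnas, k = NULL, l = NULL,
                   alphabet = c("full20", "reduced7g"), lambda = NULL,
                   grid = rls_lambda_grid(),
                   scaling = c("plain", "mean"), check_bounds = TRUE) {
  alphabet <- match.arg(alphabet)
  scaling <- match.arg(scaling)
  k <- k %||% if (alphabet == "full20") 2L else 3L
  l <- l %||% if (alphabet == "full20") 5L else 4L
  check_template_sizes(k, l, alphabet, check_bounds)
  validate_pairs(pairs, need_labels = TRUE)

  resp <- prepare_responses(pairs, proteins, rnas, k, l, alphabet)
  KP <- response_kernel_matrix(resp$protein)
  KR <- response_kernel_matrix(resp$rna)
  G <- KR[pairs$rna_id, pairs$rna_id, drop = FALSE] *
    KP[pairs$protein_id, pairs$protein_id, drop = FALSE]
  labels <- as.numeric(pairs$label)

  path <- NULL
  loo_scores <- NULL
  if (is.null(lambda)) {
    sel <- loo_lambda(G, labels, grid, scaling)
    lambda <- sel$lambda
    path <- sel$path
    loo_scores <- sel$loo_scores
  }
  co <- rls_fit(G, labels, lambda, scaling)
  fitted <- drop(G %*% co)
  ids <- pair_ids(pairs)
  names(co) <- names(fitted) <- ids

  structure(list(
    call = match.call(),
    k = as.integer(k), l = as.integer(l),
    alphabet = alphabet, scaling = scaling,
    lambda = lambda, lambda_path = path, loo_scores = loo_scores,
    coefficients = co, fitted = fitted,
    pairs = pairs, labels = labels,
    protein_responses = resp$protein, rna_responses = resp$rna
  ), class = "rpirls")
}

check_template_sizes <- function(k, l, alphabet, check_bounds = TRUE) {
  if (!is.numeric(k) || !is.numeric(l) || k != round(k) || l != round(l) ||
      k < 1 || l < 1)
    stopf("template sizes k and l must be positive integers")
  if (check_bounds) {
    kmax <- if (alphabet == "full20") 4L else 6L
    if (k > kmax)
      stopf("protein template size k = %d outside the supported range 1..%d for %s (set check_bounds = FALSE to override)",
            k, kmax, alphabet)
    if (l > 8L)
      stopf("RNA template size l = %d outside the supported range 1..8 (set check_bounds = FALSE to override)",
            l)
  }
  invisible(TRUE)
}

#' @export
print.rpirls <- function(x, ...) {
  cat("RNA-protein interaction classifier (derived kernel + regularized least squares)\n")
  cat(sprintf("  training pairs: %d (%d interacting, %d non-interacting)\n",
              length(x$labels), sum(x$labels > 0), sum(x$labels < 0)))
  cat(sprintf("  kernel: protein k = %d (%s), RNA l = %d\n",
              x$k, x$alphabet, x$l))
  cat(sprintf("  lambda: %.6g%s\n", x$lambda,
              if (is.null(x$lambda_path)) " (fixed)"
              else sprintf(" = e^%d (leave-one-out, accuracy %.3f)",
                           round(log(x$lambda)),
                           x$lambda_path$loo_accuracy[
                             x$lambda_path$lambda == x$lambda])))
  invisible(x)
}

#' @export
coef.rpirls <- function(object, ...) object$coefficients

#' @export
fitted.rpirls <- function(object, ...) object$fitted

#' @export
residuals.rpirls <- function(object, ...) object$labels - object$fitted

#' Summarize a fitted RNA-protein interaction classifier
#'
#' Reports the kernel configuration, the selected ridge parameter, and
#' training as well as leave-one-out classification quality (confusion
#' counts, sensitivity, specificity, accuracy and AUC).
#'
#' @param object an \code{\link{rpirls}} fit.
#' @param ... unused.
#' @return An object of class \code{"summary.rpirls"}.
#' @export
summary.rpirls <- function(object, ...) {
  train_conf <- confusion_counts(object$fitted, object$labels)
  out <- list(
    model = object,
    train_confusion = train_conf,
    train_metrics = classification_metrics(train_conf),
    train_auc = auc_score(object$fitted, object$labels)
  )
  if (!is.null(object$loo_scores)) {
    loo_conf <- confusion_counts(object$loo_scores, object$labels)
    out$loo_confusion <- loo_conf
    out$loo_metrics <- classification_metrics(loo_conf)
    out$loo_auc <- auc_score(object$loo_scores, object$labels)
  }
  class(out) <- "summary.rpirls"
  out
}

#' @export
print.summary.rpirls <- function(x, ...) {
  print(x$model)
  cat("\nTraining scores:\n")
  print_metric_line(x$train_confusion, x$train_metrics, x$train_auc)
  if (!is.null(x$loo_metrics)) {
    cat("Leave-one-out scores (at selected lambda):\n")
    print_metric_line(x$loo_confusion, x$loo_metrics, x$loo_auc)
  }
  invisible(x)
}

print_metric_line <- function(conf, metrics, auc) {
  cat(sprintf("  TP %d  TN %d  FP %d  FN %d | SE %.3f  SP %.3f  ACC %.3f  AUC %.3f\n",
              conf["TP"], conf["TN"], conf["FP"], conf["FN"],
              metrics["sensitivity"], metrics["specificity"],
              metrics["accuracy"], auc))
}

#' Predict interaction scores for new RNA-protein pairs
#'
#' Scores query pairs with the fitted decision function
#' \eqn{f(x) = \sum_i c_i K(x_i, x)}. A score greater than 0 predicts an
#' interaction (\eqn{+1}); a score \eqn{\le 0} predicts
#' non-interaction (\eqn{-1}). Raw scores are always returned so that
#' predictions can be ranked.
#'
#' @param object an \code{\link{rpirls}} fit.
#' @param pairs data.frame of query pairs (\code{protein_id},
#'   \code{rna_id}); if \code{NULL}, the full bipartite grid of
#'   \code{proteins} x \code{rnas} is scored.
#' @param proteins,rnas named character vectors of query sequences.
#' @param ... unused.
#' @return data.frame with columns \code{protein_id}, \code{rna_id},
#'   \code{score}, \code{label}. Query pairs whose protein (RNA) is
#'   shorter than the template size \code{k} (\code{l}) receive
#'   \code{NA} with a warning; the remaining rows are still scored.
#' @export
predict.rpirls <- function(object, pairs = NULL, proteins, rnas, ...) {
  proteins <- canonicalize_protein(proteins)
  rnas <- canonicalize_rna(rnas)
  if (is.null(pairs)) {
    pairs <- expand.grid(protein_id = names(proteins), rna_id = names(rnas),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  }
  validate_pairs(pairs, proteins, rnas)
  prot_use <- proteins[unique(pairs$protein_id)]
  if (object$alphabet == "reduced7g") prot_use <- reduce_protein(prot_use)
  rna_use <- rnas[unique(pairs$rna_id)]

  ok_p <- nchar(prot_use) >= object$k
  ok_r <- nchar(rna_use) >= object$l
  scorable <- pairs$protein_id %in% names(prot_use)[ok_p] &
    pairs$rna_id %in% names(rna_use)[ok_r]
  if (any(!scorable))
    warning(sprintf("%d query pair(s) skipped (sequence shorter than template size): %s",
                    sum(!scorable), abbrev(pair_ids(pairs[!scorable, ]))),
            call. = FALSE)

  scores <- rep(NA_real_, nrow(pairs))
  if (any(scorable)) {
    qp <- lapply(prot_use[ok_p], kmer_frequencies, size = object$k)
    qr <- lapply(rna_use[ok_r], kmer_frequencies, size = object$l)
    KPq <- response_kernel_matrix(object$protein_responses, qp)
    KRq <- response_kernel_matrix(object$rna_responses, qr)
    sub <- pairs[scorable, , drop = FALSE]
    tr <- object$pairs
    # m x q matrix of pair-kernel values between training and query pairs
    A <- KRq[tr$rna_id, sub$rna_id, drop = FALSE] *
      KPq[tr$protein_id, sub$protein_id, drop = FALSE]
    scores[scorable] <- drop(crossprod(A, object$coefficients))
  }
  data.frame(
    protein_id = pairs$protein_id,
    rna_id = pairs$rna_id,
    score = scores,
    label = ifelse(is.na(scores), NA_integer_, ifelse(scores > 0, 1L, -1L)),
    stringsAsFactors = FALSE
  )
}

#' Plot leave-one-out accuracy across the ridge grid
#'
#' For fits with automatic \eqn{\lambda} selection, plots leave-one-out
#' classification accuracy against \eqn{\log \lambda} and marks the
#' selected value. For fixed-\eqn{\lambda} fits, shows the training
#' score distribution by class around the decision threshold at 0.
#'
#' @param x an \code{\link{rpirls}} fit.
#' @param ... passed to the underlying plotting function.
#' @return \code{x}, invisibly.
#' @export
plot.rpirls <- function(x, ...) {
  if (!is.null(x$lambda_path)) {
    graphics::plot(log(x$lambda_path$lambda), x$lambda_path$loo_accuracy,
                   type = "b", pch = 16, cex = 0.7,
                   xlab = expression(log(lambda)),
                   ylab = "leave-one-out accuracy", ...)
    graphics::abline(v = log(x$lambda), lty = 2)
  } else {
    graphics::boxplot(split(x$fitted, ifelse(x$labels > 0, "+1", "-1")),
                      ylab = "training score", xlab = "class", ...)
    graphics::abline(h = 0, lty = 2)
  }
  invisible(x)
}

#' Save or load a fitted classifier
#'
#' The archive is a self-describing versioned list (kernel
#' configuration, ridge parameter, coefficients, training pair ids and
#' the training k-mer profiles); reloading reproduces prediction scores
#' bit for bit on the same platform.
#'
#' @param object an \code{\link{rpirls}} fit.
#' @param path file path for the model archive.
#' @return \code{save_rpirls} returns \code{path} invisibly;
#'   \code{load_rpirls} returns the restored \code{"rpirls"} object.
#' @export
save_rpirls <- function(object, path) {
  stopifnot(inherits(object, "rpirls"))
  payload <- unclass(object)
  payload$call <- NULL
  archive <- list(schema = "rpirls-model", schema_version = 1L,
                  package_version = as.character(utils::packageVersion("rpikrls")),
                  model = payload)
  saveRDS(archive, path)
  invisible(path)
}

#' @rdname save_rpirls
#' @export
load_rpirls <- function(path) {
  archive <- readRDS(path)
  if (!identical(archive$schema, "rpirls-model"))
    stopf("'%s' is not an rpirls model archive", path)
  if (!identical(archive$schema_version, 1L))
    stopf("unsupported model archive version: %s", archive$schema_version)
  model <- archive$model
  model$call <- NULL
  structure(model, class = "rpirls")
}
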