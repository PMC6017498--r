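#' Default ridge-parameter grid
#'
#' The grid searched by leave-one-out selection:
#' \eqn{\lambda = e^n} for \eqn{n = -15, \ldots, 15} (31 values,
#' ascending).
#'
#' @return Numeric vector of 31 candidate \eqn{\lambda} values.
#' @export
rls_lambda_grid <- function() exp(-15:15)

#' Fit kernel regularized least squares on a precomputed Gram matrix
#'
#' Solves \eqn{(K + \lambda I) c = y} (the representer form of the
#' squared-loss objective with RKHS penalty \eqn{\lambda \|f\|_K^2});
#' the decision function is \eqn{f(x) = \sum_i c_i K(x_i, x)}.
#'
#' @param gram symmetric positive semidefinite kernel matrix.
#' @param labels numeric response vector (\eqn{\pm 1} for
#'   classification).
#' @param lambda positive ridge parameter.
#' @param scaling \code{"plain"} solves \eqn{(K+\lambda I)c=y};
#'   \code{"mean"} uses the mean-loss convention \eqn{(K+\lambda m I)c=y}
#'   (the two conventions differ only by a rescaling of \eqn{\lambda}).
#' @return Numeric coefficient vector \code{c} (named by the Gram row
#'   names, if any).
#' @export
rls_fit <- function(gram, labels, lambda, scaling = c("plain", "mean")) {
  scaling <- match.arg(scaling)
  m <- check_rls_inputs(gram, labels)
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0)
    stopf("lambda must be a single positive number")
  ridge <- if (scaling == "mean") lambda * m else lambda
  co <- solve(gram + diag(ridge, m), labels)
  res <- sqrt(sum((gram %*% co + ridge * co - labels)^2))
  stopifnot(res <= 1e-8 * sqrt(sum(labels^2)) + 1e-12)
  co <- drop(co)
  names(co) <- rownames(gram)
  co
}

check_rls_inputs <- function(gram, labels) {
  stopifnot(is.matrix(gram), nrow(gram) == ncol(gram))
  m <- nrow(gram)
  if (length(labels) != m)
    stopf("labels length (%d) does not match Gram size (%d)",
          length(labels), m)
  if (any(is.na(labels))) stopf("labels must not be missing")
  m
}

#' Leave-one-out selection of the ridge parameter
#'
#' For every candidate \eqn{\lambda} the held-out prediction of each
#' training point is obtained in closed form from the hat matrix
#' \eqn{H = K (K + \lambda I)^{-1}}:
#' \deqn{\hat y_i^{(-i)} = \frac{(Hy)_i - H_{ii} y_i}{1 - H_{ii}},}
#' so a single eigendecomposition of \eqn{K} serves the whole grid and no
#' model is ever refitted. The selected \eqn{\lambda} maximizes
#' leave-one-out classification accuracy of \eqn{sign} predictions
#' (a score \eqn{\le 0} predicts \eqn{-1}); ties are broken toward the
#' largest (most regularized) \eqn{\lambda}.
#'
#' @inheritParams rls_fit
#' @param grid ascending vector of candidate \eqn{\lambda} values.
#' @return A list with \code{lambda} (the selected value), \code{path}
#'   (data.frame of \code{lambda} and \code{loo_accuracy}), and
#'   \code{loo_scores} (held-out scores at the selected \eqn{\lambda}).
#' @export
loo_lambda <- function(gram, labels, grid = rls_lambda_grid(),
                       scaling = c("plain", "mean")) {
  scaling <- match.arg(scaling)
  m <- check_rls_inputs(gram, labels)
  if (m < 2L) stopf("leave-one-out selection needs at least 2 points")
  if (is.unsorted(grid)) grid <- sort(grid)
  eg <- eigen(gram, symmetric = TRUE)
  V <- eg$vectors
  d <- eg$values
  vty <- drop(crossprod(V, labels))
  V2 <- V^2
  loo_at <- function(lambda) {
    ridge <- if (scaling == "mean") lambda * m else lambda
    shrink <- d / (d + ridge)
    fitted <- drop(V %*% (shrink * vty))
    hii <- drop(V2 %*% shrink)
    denom <- 1 - hii
    loo <- ifelse(abs(denom) < 1e-12, 0, (fitted - hii * labels) / denom)
    loo
  }
  scores <- vapply(grid, loo_at, numeric(m))
  acc <- colMeans((scores > 0) == (labels > 0))
  best <- max(which(acc == max(acc)))  # tie -> larger lambda
  list(
    lambda = grid[best],
    path = data.frame(lambda = grid, loo_accuracy = acc),
    loo_scores = scores[, best]
  )
}
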