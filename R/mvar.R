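# Least-squares MVAR fitting, residual covariance, order feasibility / AIC.

#' Feasibility of an MVAR model order
#'
#' A K-variate order-p MVAR least-squares fit has a non-singular estimation
#' equation only if \code{N - p >= K * p}.
#'
#' @param K number of series.
#' @param N number of temporal samples.
#' @param p model order.
#' @return TRUE iff the fit is feasible.
#' @examples
#' feasibleOrder(999, 1000, 1) # TRUE
#' feasibleOrder(1000, 1000, 1) # FALSE
#' @export
feasibleOrder <- function(K, N, p) {
  stopifnot(K >= 1, N >= 1, p >= 1)
  (N - p) >= K * p
}

# Core least-squares fit on already-centered data y (K x N, rows = series).
# Regression per target equation of y(n) on y(n-1), ..., y(n-p), solved via a
# pivoted QR decomposition (lm.fit). With allowRankDeficient the fitted values
# are the (always unique) projection onto the regressor column space even when
# the coefficients are not identified; aliased coefficients are set to zero.
.mvarLs <- function(y, p, allowRankDeficient = FALSE) {
  K <- nrow(y); N <- ncol(y)
  Y <- t(y[, (p + 1L):N, drop = FALSE])            # (N-p) x K
  X <- matrix(0, N - p, K * p)
  for (r in seq_len(p))
    X[, ((r - 1L) * K + 1L):(r * K)] <- t(y[, (p + 1L - r):(N - r), drop = FALSE])
  fit <- lm.fit(X, Y)
  if (fit$rank < ncol(X) && !allowRankDeficient) {
    d <- abs(diag(fit$qr$qr))
    stop(sprintf(
      "rank-deficient regressor matrix (rank %d < %d; condition estimate %.3g); refusing fit",
      fit$rank, ncol(X), max(d) / max(min(d[d > 0]), .Machine$double.xmin)))
  }
  B <- as.matrix(fit$coefficients)                 # (K*p) x K, NA when aliased
  B[is.na(B)] <- 0
  dimnames(B) <- NULL
  A <- lapply(seq_len(p), function(r) t(B[((r - 1L) * K + 1L):(r * K), , drop = FALSE]))
  res <- t(as.matrix(fit$residuals))               # K x (N-p)
  fitv <- t(as.matrix(fit$fitted.values))
  dimnames(res) <- NULL
  dimnames(fitv) <- NULL
  list(A = A,
       residuals = res,
       fitted = fitv,
       sigma = tcrossprod(res) / (N - p),
       rank = fit$rank)
}

#' Fit a multivariate autoregressive model by least squares
#'
#' Fits the order-p MVAR model to a K-by-N data matrix (rows = series) by
#' multivariate least squares over time points \code{n = p+1, ..., N}. Rows
#' are mean-centered internally and no intercept is estimated, so the fitted
#' values plus residuals reproduce the centered data exactly. The fit is
#' solved through a pivoted orthogonal (QR) decomposition; an infeasible order
#' (\code{N - p < K * p}) or a rank-deficient regressor matrix is refused with
#' a diagnostic.
#'
#' @param y K-by-N numeric matrix of time series, rows = series.
#' @param p model order.
#' @return An [MvarModel-class].
#' @examples
#' y <- simulateMvar(new("ArCoefficients", A = list(diag(0.5, 2)),
#'                       eta = 1L, order = 1L), N = 300, seed = 2)
#' fit <- fitMvar(y, p = 1)
#' round(coefMatrices(fit)[[1]], 2)
#' @export
fitMvar <- function(y, p) {
  y <- as.matrix(y)
  p <- as.integer(p)
  K <- nrow(y); N <- ncol(y)
  if (!feasibleOrder(K, N, p))
    stop(sprintf("infeasible model order: need N - p >= K * p, got %d - %d < %d * %d",
                 N, p, K, p))
  center <- rowMeans(y)
  ls <- .mvarLs(y - center, p)
  new("MvarModel", p = p, A = ls$A, residuals = ls$residuals,
      fitted = ls$fitted, sigma = (ls$sigma + t(ls$sigma)) / 2,
      center = center)
}

#' Residual covariance matrix
#'
#' Covariance of an MVAR residual matrix (rows = series, columns = the N - p
#' usable time points), normalized by the number of columns (the
#' maximum-likelihood convention; the Granger causality index is a ratio of
#' diagonal entries so the convention cancels there). Residual means are not
#' subtracted: the models are intercept-free fits to row-centered data.
#'
#' @param e residual matrix (K rows) or an [MvarModel-class].
#' @return Symmetric positive semidefinite K-by-K matrix.
#' @export
setGeneric("residualCovariance", function(e) standardGeneric("residualCovariance"))

#' @describeIn residualCovariance covariance of a raw residual matrix.
#' @export
setMethod("residualCovariance", "matrix", function(e) {
  if (ncol(e) < 2L) stop("need at least 2 residual columns")
  S <- tcrossprod(e) / ncol(e)
  (S + t(S)) / 2
})

#' @describeIn residualCovariance stored covariance of a fitted model.
#' @export
setMethod("residualCovariance", "MvarModel", function(e) e@sigma)

#' Select an MVAR model order by AIC
#'
#' Computes, for each candidate order p, the multivariate Akaike information
#' criterion \code{(N - p) * log det Sigma(p) + 2 * K^2 * p} from the fitted
#' residual covariance and returns the minimizing order (smallest order on
#' ties). Candidate orders that violate the feasibility condition are refused.
#'
#' @param y K-by-N data matrix, rows = series.
#' @param pMax largest candidate order; candidates are 1..pMax.
#' @return Integer, the selected order.
#' @export
selectOrderAic <- function(y, pMax) {
  y <- as.matrix(y)
  K <- nrow(y); N <- ncol(y)
  pMax <- as.integer(pMax)
  stopifnot(pMax >= 1L)
  feas <- vapply(seq_len(pMax), function(p) feasibleOrder(K, N, p), logical(1))
  if (!any(feas)) stop("no feasible candidate order: N - p >= K * p fails for all p in 1..", pMax)
  if (!all(feas)) stop(sprintf("candidate orders %s violate N - p >= K * p",
                               paste(which(!feas), collapse = ",")))
  aic <- vapply(seq_len(pMax), function(p) {
    fit <- fitMvar(y, p)
    ld <- determinant(fit@sigma, logarithm = TRUE)
    as.numeric((N - p) * ld$modulus + 2 * K^2 * p)
  }, numeric(1))
  which.min(aic)
}
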