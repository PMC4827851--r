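# Large-scale Granger Causality: PCA reduction, low-dimensional MVAR,
# back-projection of predictions, and column-deleted reduced models.

#' PCA reduction of a multivariate time series
#'
#' Row-wise principal component analysis of a D-by-N data matrix. Rows are
#' mean-centered (and optionally standardized) internally; the decomposition
#' is computed on the spatial (D-by-D) covariance, or equivalently on the
#' temporal (N-by-N) Gram matrix when N < D (the two sides share the non-zero
#' spectrum). The number of retained components C is the smallest count whose
#' cumulative eigenvalue fraction reaches \code{varTarget}. Eigenvector signs
#' are fixed deterministically by making the largest-magnitude loading of each
#' component positive; the lsGCI is invariant to this choice.
#'
#' @param y D-by-N data matrix, rows = series.
#' @param varTarget target cumulative variance fraction in (0, 1];
#'   \code{varTarget = 1} retains the full basis (C = D for full-rank data).
#' @param standardize also scale rows to unit variance before the
#'   decomposition (off by default; the benchmark uses plain PCA of the
#'   centered data).
#' @return A [PcaReduction-class].
#' @examples
#' y <- matrix(rnorm(20 * 200), 20, 200)
#' red <- pcaReduce(y, 0.8)
#' retainedComponents(red)
#' @export
pcaReduce <- function(y, varTarget, standardize = FALSE) {
  if (!is.numeric(varTarget) || length(varTarget) != 1L ||
      varTarget <= 0 || varTarget > 1)
    stop("varTarget must be a single value in (0, 1]")
  y <- as.matrix(y)
  D <- nrow(y); N <- ncol(y)
  center <- rowMeans(y)
  yc <- y - center
  if (standardize) {
    s <- sqrt(rowSums(yc^2) / (N - 1))
    if (any(s == 0)) stop("cannot standardize constant rows")
    yc <- yc / s
  }
  if (D <= N) {
    ee <- eigen(tcrossprod(yc) / (N - 1), symmetric = TRUE)
    vals <- ee$values
    vecs <- ee$vectors
  } else {
    ee <- eigen(crossprod(yc) / (N - 1), symmetric = TRUE)
    vals <- c(ee$values[seq_len(N)], rep(0, D - N))
    pos <- which(ee$values > max(ee$values) * 1e-12)
    vecs <- matrix(0, D, D)
    vecs[, pos] <- yc %*% ee$vectors[, pos] %*%
      diag(1 / sqrt(ee$values[pos] * (N - 1)), length(pos))
  }
  vals[vals < 0] <- 0
  tot <- sum(vals)
  if (tot <= 0) stop("data have zero variance; PCA undefined")
  ratio <- cumsum(vals) / tot
  C <- which(ratio >= varTarget - 1e-12)[1]
  if (is.na(C)) C <- D
  W <- t(vecs[, seq_len(C), drop = FALSE])
  flip <- apply(W, 1L, function(w) sign(w[which.max(abs(w))]))
  flip[flip == 0] <- 1
  W <- W * flip
  new("PcaReduction", W = W, eigenvalues = vals, nComponents = as.integer(C),
      varExplained = ratio[C], center = center)
}

#' Back-project component-space predictions into the observation space
#'
#' Left-multiplies by the Moore-Penrose pseudoinverse of the mixing matrix.
#' For a truncated mixing matrix with orthonormal rows the pseudoinverse is
#' its transpose; for column-deleted mixing matrices the general pseudoinverse
#' is used.
#'
#' @param xHat C-by-N matrix of component-space values.
#' @param W C-by-D mixing matrix.
#' @return D-by-N back-projected matrix \code{ginv(W) %*% xHat}.
#' @export
backProject <- function(xHat, W) {
  if (is(W, "PcaReduction")) W <- W@W
  if (nrow(W) != nrow(xHat)) stop("W and xHat must agree on the component count")
  MASS::ginv(W) %*% xHat
}

#' Large-scale Granger causality index
#'
#' Computes the lsGCI connectivity matrix of a D-by-N time series: (1) the
#' centered data are projected onto the leading C principal components,
#' \code{x = W y}; (2) a C-variate order-p MVAR model is fitted and its
#' predictions back-projected, giving high-dimensional residuals
#' \code{e(n) = y(n) - pinv(W) xhat(n)}; (3) for each candidate source i, row
#' i of the data and column i of W are deleted, the C-variate model is refitted
#' on \code{x^(i-) = W^(i-) y^(i-)} and back-projected through
#' \code{pinv(W^(i-))}; (4) the index is the log ratio of the high-dimensional
#' residual variance diagonals, \code{gamma[j, i] =
#' log(sigmaReduced_j / sigmaFull_j)} for j != i. D + 1 low-dimensional fits
#' in total. Residual covariances are computed over \code{n = p+1, ..., N}.
#'
#' At \code{varTarget = 1} (C = D) the procedure reproduces the classical GCI
#' exactly; at C < D finite-sample values can be negative (the back-projected
#' models are not nested least-squares fits) and are never clipped.
#'
#' @param y D-by-N data matrix, rows = series (mean-centered internally).
#' @param p MVAR model order.
#' @param varTarget cumulative variance fraction in (0, 1] for the reduction.
#' @param standardize passed to [pcaReduce()].
#' @return A [ConnectivityMatrix-class] with estimator tag \code{"lsgc"}
#'   (\code{"gci"} when C = D).
#' @examples
#' y <- matrix(rnorm(20 * 300), 20, 300)
#' cm <- lsGci(y, p = 1, varTarget = 0.8)
#' @export
lsGci <- function(y, p = 1L, varTarget = 0.8, standardize = FALSE) {
  y <- as.matrix(y)
  p <- as.integer(p)
  D <- nrow(y); N <- ncol(y)
  yc <- .centerRows(y)
  red <- pcaReduce(yc, varTarget, standardize = standardize)
  C <- red@nComponents
  if ((N - p) < C * p)
    stop(sprintf("infeasible reduction: need N - p >= C * p, got %d - %d < %d * %d",
                 N, p, C, p))
  if (standardize) yc <- yc / sqrt(rowSums(yc^2) / (N - 1))
  W <- red@W
  x <- W %*% yc
  full <- .mvarLs(x, p, allowRankDeficient = TRUE)
  span <- (p + 1L):N
  eFull <- yc[, span, drop = FALSE] - t(W) %*% full$fitted # pinv(W) = t(W)
  sFull <- rowSums(eFull^2) / (N - p)
  gamma <- matrix(NA_real_, D, D)
  for (i in seq_len(D)) {
    Wi <- W[, -i, drop = FALSE]
    xi <- Wi %*% yc[-i, , drop = FALSE]
    redFit <- .mvarLs(xi, p, allowRankDeficient = TRUE)
    eRed <- yc[-i, span, drop = FALSE] - MASS::ginv(Wi) %*% redFit$fitted
    sRed <- rowSums(eRed^2) / (N - p)
    gamma[-i, i] <- log(sRed / sFull[-i])
  }
  new("ConnectivityMatrix", gamma = gamma, p = p, nComponents = C,
      varExplained = red@varExplained,
      estimator = if (C == D) "gci" else "lsgc")
}
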