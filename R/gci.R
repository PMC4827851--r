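# Classical multivariate Granger Causality Index.

#' Classical multivariate Granger causality index
#'
#' For each candidate source series i, the full D-variate MVAR model is
#' compared with a (D-1)-variate refit on the data with row i deleted; the
#' index from i to j is the log ratio of the target residual variances,
#' \code{gamma[j, i] = log(sigmaReduced_j / sigmaFull_j)}. One full fit plus D
#' reduced fits (D + 1 least-squares fits in total). In sample the index is
#' nonnegative for every pair, because each reduced target equation uses a
#' subset of the full equation's predictors.
#'
#' @param y D-by-N data matrix, rows = series (mean-centered internally).
#' @param p MVAR model order.
#' @return A [ConnectivityMatrix-class] with estimator tag \code{"gci"},
#'   orientation \code{gamma[target, source]}, diagonal NA.
#' @examples
#' net <- generateGroundTruthNetwork(100, seed = 3)
#' y <- simulateMvar(assignArCoefficients(net, 3), N = 1000, seed = 3)
#' \donttest{g <- classicalGci(y, p = 1)}
#' @export
classicalGci <- function(y, p = 1L) {
  y <- as.matrix(y)
  p <- as.integer(p)
  D <- nrow(y); N <- ncol(y)
  if (!feasibleOrder(D, N, p))
    stop(sprintf("infeasible: classical GCI needs N - p >= D * p, got %d - %d < %d * %d",
                 N, p, D, p))
  yc <- .centerRows(y)
  full <- .mvarLs(yc, p)
  sFull <- diag(full$sigma)
  gamma <- matrix(NA_real_, D, D)
  for (i in seq_len(D)) {
    red <- .mvarLs(yc[-i, , drop = FALSE], p)
    gamma[-i, i] <- log(diag(red$sigma) / sFull[-i])
  }
  new("ConnectivityMatrix", gamma = gamma, p = p, nComponents = D,
      varExplained = 1, estimator = "gci")
}
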