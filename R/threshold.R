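# Dichotomization of weighted connectivity matrices and ROC edge-recovery
# evaluation. All candidate edges are off-diagonal cells; self-connections are
# never candidates.

#' Percentile threshold of the edge weight distribution
#'
#' q-th percentile of the off-diagonal connectivity weights, computed with the
#' linear-interpolation convention of \code{quantile(type = 7)}. The
#' operating points 90, 95 and 98 remove roughly 90/95/98% of candidate
#' edges under the strict-inequality retention rule of [binarize()].
#'
#' @param gamma a [ConnectivityMatrix-class] or numeric matrix.
#' @param q percentile in (0, 100).
#' @return The threshold value.
#' @export
percentileThreshold <- function(gamma, q) {
  stopifnot(is.numeric(q), length(q) == 1L, q > 0, q < 100)
  w <- .offDiagonal(.asGamma(gamma))
  unname(quantile(w[is.finite(w)], probs = q / 100, type = 7))
}

#' Dichotomize a weighted connectivity matrix
#'
#' Keeps a directed edge iff its weight is strictly greater than the
#' threshold (ties at the threshold are dropped, so a q-th percentile
#' threshold removes approximately q% of candidate edges); all surviving
#' edges get weight 1 and the diagonal is always 0.
#'
#' @param gamma a [ConnectivityMatrix-class] or numeric matrix.
#' @param threshold cutoff value.
#' @return Integer binary matrix in the same orientation as the input.
#' @export
binarize <- function(gamma, threshold) {
  g <- .asGamma(gamma)
  B <- (g > threshold) + 0L
  B[!is.finite(g)] <- 0L
  diag(B) <- 0L
  B
}

#' Cohen's-kappa-optimal dichotomization threshold
#'
#' Sweeps every unique off-diagonal weight as a cutoff (strict-inequality
#' retention) and returns the cutoff maximizing Cohen's kappa between the
#' binarized matrix and the ground-truth adjacency, over off-diagonal cells
#' only. Ties are broken toward the lowest such cutoff (the densest of the
#' equally good networks).
#'
#' @param gamma a [ConnectivityMatrix-class] or numeric matrix.
#' @param truth a [ModularNetwork-class] or binary adjacency matrix of the
#'   same dimension.
#' @return The optimal threshold, with attributes \code{kappa} (the maximal
#'   kappa) and \code{nEdges} (edges retained at the optimum).
#' @export
kappaOptimalThreshold <- function(gamma, truth) {
  g <- .asGamma(gamma)
  A <- .asAdjacency(truth)
  if (!all(dim(g) == dim(A))) stop("gamma and truth must have the same dimension")
  off <- row(g) != col(g)
  w <- g[off]
  status <- A[off]
  P <- sum(status); n <- length(status)
  if (P == 0L || P == n)
    stop("degenerate truth (all-positive or all-negative); kappa undefined")
  ord <- order(w, decreasing = TRUE)
  ws <- w[ord]
  cumTP <- cumsum(status[ord])
  r <- rle(ws)
  ends <- cumsum(r$lengths)
  npos <- ends - r$lengths                     # edges kept at cutoff = value (strict >)
  TP <- c(0, cumTP)[npos + 1L]
  po <- (2 * TP + n - P - npos) / n            # (TP + TN) / n
  pe <- (npos * P + (n - npos) * (n - P)) / n^2
  kap <- (po - pe) / (1 - pe)
  best <- which(kap == max(kap))
  pick <- best[length(best)]                   # values are decreasing: last = lowest cutoff
  structure(r$values[pick], kappa = kap[pick], nEdges = npos[pick])
}

#' Weak connectedness of a directed binary network
#'
#' TRUE iff the network is weakly connected (its symmetrized version is one
#' connected component) with no isolated vertices. Used as the admissibility
#' filter for dichotomization thresholds; the pipeline reports, rather than
#' adjusts, inadmissible thresholds.
#'
#' @param net a binary adjacency matrix, [ModularNetwork-class] or igraph.
#' @return Logical.
#' @export
checkConnectedness <- function(net) {
  A <- .asAdjacency(net)
  if (nrow(A) < 2L) return(TRUE)
  g <- .asGraph(A)
  igraph::is_connected(g, mode = "weak")
}

#' ROC curve of edge recovery against a ground-truth network
#'
#' Treats the presence of a directed edge in the truth adjacency as the
#' positive status and the connectivity weight as the predictor, over all
#' off-diagonal cells. The curve sweeps all cutoffs (tied weights form a
#' single step); the AUC is the trapezoidal area, which equals the
#' Mann-Whitney U statistic of the weights grouped by status.
#'
#' @param gamma a [ConnectivityMatrix-class] or numeric matrix.
#' @param truth a [ModularNetwork-class] or binary adjacency matrix.
#' @return List with elements \code{thresholds} (unique weights, decreasing),
#'   \code{tpr}, \code{fpr} (each starting at 0) and \code{auc}.
#' @examples
#' net <- generateGroundTruthNetwork(100, seed = 4)
#' rocCurve(adjacency(net) + 0.0, net)$auc # weights = truth: AUC 1
#' @export
rocCurve <- function(gamma, truth) {
  g <- .asGamma(gamma)
  A <- .asAdjacency(truth)
  if (!all(dim(g) == dim(A))) stop("gamma and truth must have the same dimension")
  off <- row(g) != col(g)
  w <- g[off]
  status <- A[off]
  P <- sum(status); Nn <- length(status) - P
  if (P == 0L || Nn == 0L) stop("degenerate status set; ROC undefined")
  ord <- order(w, decreasing = TRUE)
  ws <- w[ord]
  tp <- cumsum(status[ord])
  fp <- seq_along(ws) - tp
  ends <- cumsum(rle(ws)$lengths)
  tpr <- c(0, tp[ends] / P)
  fpr <- c(0, fp[ends] / Nn)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(thresholds = ws[ends], tpr = tpr, fpr = fpr, auc = auc)
}
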