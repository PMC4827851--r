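# S4 classes for the central data objects. Orientation convention everywhere:
# adjacency[i, j] = 1 iff there is a directed edge j -> i.

#' Modular ground-truth network
#'
#' A directed binary network with planted, non-overlapping modules, as
#' produced by [generateGroundTruthNetwork()]. Module sizes lie in 10..15,
#' adjacency column sums are bounded by 15, every vertex keeps at least 4
#' intra-module in- and out-edges and at most 4 inter-module in- and
#' out-edges, and the diagonal is zero. These constraints are enforced by the
#' class validity method; construction fails rather than silently relaxing
#' them.
#'
#' @slot adjacency integer matrix, \code{adjacency[i, j] = 1} iff edge
#'   \code{j -> i}.
#' @slot labels integer vector of planted module ids (1-based, contiguous).
#' @slot moduleSizes integer vector of module sizes, summing to D.
#' @slot params list recording the generation constraints (D, pInt, pExt,
#'   seed, orientation note, off-benchmark flag).
#' @exportClass ModularNetwork
setClass("ModularNetwork",
  representation(
    adjacency = "matrix",
    labels = "integer",
    moduleSizes = "integer",
    params = "list"
  )
)

setValidity("ModularNetwork", function(object) {
  A <- object@adjacency
  lab <- object@labels
  sizes <- object@moduleSizes
  D <- nrow(A)
  msg <- character()
  if (ncol(A) != D) msg <- c(msg, "adjacency must be square")
  if (!all(A %in% c(0L, 1L))) msg <- c(msg, "adjacency must be binary")
  if (any(diag(A) != 0)) msg <- c(msg, "adjacency diagonal must be zero")
  if (length(lab) != D) msg <- c(msg, "labels length must equal D")
  if (length(msg)) return(msg)
  if (any(sizes < 10L) || any(sizes > 15L))
    msg <- c(msg, "every module size must lie in [10, 15]")
  if (sum(sizes) != D) msg <- c(msg, "module sizes must sum to D")
  if (!identical(as.integer(tabulate(lab, nbins = length(sizes))),
                 as.integer(sizes)))
    msg <- c(msg, "labels must agree with moduleSizes")
  if (any(colSums(A) > 15L)) msg <- c(msg, "adjacency column sums must be <= 15")
  same <- outer(lab, lab, "==")
  intra <- A * same
  inter <- A * !same
  if (any(rowSums(intra) < 4L)) msg <- c(msg, "each vertex needs >= 4 intra-module in-edges")
  if (any(colSums(intra) < 4L)) msg <- c(msg, "each vertex needs >= 4 intra-module out-edges")
  if (any(rowSums(inter) > 4L)) msg <- c(msg, "each vertex allows <= 4 inter-module in-edges")
  if (any(colSums(inter) > 4L)) msg <- c(msg, "each vertex allows <= 4 inter-module out-edges")
  if (length(msg)) msg else TRUE
})

#' Autoregressive coefficients of a simulated MVAR process
#'
#' Coefficient matrices of a p-th order MVAR process whose support matches a
#' ground-truth adjacency. Non-zero entries have magnitude \code{0.99 / eta},
#' where \code{eta} is the maximum adjacency column sum; this bounds the
#' maximum absolute row sum of the coefficient matrix near 0.99 and thereby
#' keeps the process stationary with a wide margin.
#'
#' @slot A list of p square coefficient matrices.
#' @slot eta integer, the maximum adjacency column sum used for scaling
#'   (0 for an edgeless network).
#' @slot order integer model order p.
#' @exportClass ArCoefficients
setClass("ArCoefficients",
  representation(A = "list", eta = "integer", order = "integer")
)

setValidity("ArCoefficients", function(object) {
  if (length(object@A) != object@order) return("length(A) must equal order")
  dims <- vapply(object@A, dim, integer(2))
  if (any(dims != dims[1, 1])) return("all coefficient matrices must be square of equal size")
  TRUE
})

#' Fitted multivariate autoregressive model
#'
#' Least-squares fit of a p-th order K-variate MVAR model to row-mean-centered
#' data (no intercept). Residuals and fitted values cover time points
#' \code{n = p+1, ..., N}; the fitted values plus residuals reproduce the
#' centered data exactly. The residual covariance uses the \code{1/(N-p)}
#' normalization.
#'
#' @slot p integer model order.
#' @slot A list of p K-by-K coefficient matrices.
#' @slot residuals K-by-(N-p) residual matrix (rows = series).
#' @slot fitted K-by-(N-p) fitted-value matrix.
#' @slot sigma K-by-K residual covariance.
#' @slot center numeric vector of the row means removed before fitting.
#' @exportClass MvarModel
setClass("MvarModel",
  representation(
    p = "integer",
    A = "list",
    residuals = "matrix",
    fitted = "matrix",
    sigma = "matrix",
    center = "numeric"
  )
)

setValidity("MvarModel", function(object) {
  K <- nrow(object@sigma)
  if (ncol(object@sigma) != K) return("sigma must be square")
  if (max(abs(object@sigma - t(object@sigma))) > 1e-8 * (1 + max(abs(object@sigma))))
    return("sigma must be symmetric")
  if (nrow(object@residuals) != K) return("residual rows must match sigma")
  TRUE
})

#' Truncated PCA reduction
#'
#' Row-wise PCA of a D-by-N time-series matrix: the C-by-D truncated mixing
#' matrix W holds the leading eigenvectors of the spatial covariance as rows
#' (orthonormal), with eigenvector signs fixed deterministically (largest
#' absolute loading positive).
#'
#' @slot W C-by-D truncated mixing matrix with orthonormal rows.
#' @slot eigenvalues all D eigenvalues in descending order (tiny negative
#'   values clamped to zero).
#' @slot C integer number of retained components.
#' @slot varExplained cumulative eigenvalue fraction retained by the first C
#'   components.
#' @slot center row means removed before the decomposition.
#' @exportClass PcaReduction
setClass("PcaReduction",
  representation(
    W = "matrix",
    eigenvalues = "numeric",
    nComponents = "integer",
    varExplained = "numeric",
    center = "numeric"
  )
)

setValidity("PcaReduction", function(object) {
  if (nrow(object@W) != object@nComponents) return("W must have C rows")
  G <- tcrossprod(object@W)
  if (max(abs(G - diag(nrow(G)))) > 1e-6) return("rows of W must be orthonormal")
  if (is.unsorted(rev(object@eigenvalues))) return("eigenvalues must be descending")
  TRUE
})

#' Directed connectivity matrix of (ls)GCI values
#'
#' D-by-D matrix of Granger causality indices; entry \code{gamma[j, i]} holds
#' the influence of series i on series j (same target-row/source-column
#' orientation as the adjacency convention). The diagonal is undefined and
#' stored as NA. Classical GCI values are nonnegative in sample; lsGCI values
#' can be negative in finite samples (the back-projected models are not nested
#' least-squares fits) and are never clipped.
#'
#' @slot gamma D-by-D numeric matrix with NA diagonal.
#' @slot p integer MVAR model order.
#' @slot C integer number of PCA components used (D for the classical GCI).
#' @slot varExplained variance fraction retained (1 for classical GCI).
#' @slot estimator character tag, \code{"gci"} or \code{"lsgc"}.
#' @exportClass ConnectivityMatrix
setClass("ConnectivityMatrix",
  representation(
    gamma = "matrix",
    p = "integer",
    nComponents = "integer",
    varExplained = "numeric",
    estimator = "character"
  )
)

setValidity("ConnectivityMatrix", function(object) {
  g <- object@gamma
  if (nrow(g) != ncol(g)) return("gamma must be square")
  if (!all(is.na(diag(g)))) return("gamma diagonal must be masked (NA)")
  off <- g[row(g) != col(g)]
  if (any(!is.finite(off))) return("off-diagonal gamma entries must be finite")
  TRUE
})

#' Vertex partition into modules
#'
#' A labelling of a fixed vertex set into modules. Labels are canonical:
#' contiguous integers starting at 0, numbered by first appearance. All
#' partition metrics in the package are invariant under relabelling.
#'
#' @slot labels integer vector of module ids, contiguous from 0.
#' @slot k integer number of modules.
#' @slot algorithm character tag of the producing algorithm (or "planted").
#' @slot modularity modularity of the partition at selection time (NA when
#'   not computed).
#' @exportClass Partition
setClass("Partition",
  representation(
    labels = "integer",
    k = "integer",
    algorithm = "character",
    modularity = "numeric"
  )
)

setValidity("Partition", function(object) {
  lab <- object@labels
  if (length(lab) == 0L) return("empty partition")
  u <- sort(unique(lab))
  if (!identical(u, seq(0L, length.out = length(u))))
    return("labels must be contiguous integers starting at 0")
  if (object@k != length(u)) return("k must equal the number of distinct labels")
  TRUE
})

#' Construct a Partition from arbitrary labels
#'
#' Canonicalizes any vector of module labels (integers, characters or a
#' factor) to contiguous 0-based ids ordered by first appearance.
#'
#' @param labels vector of module labels, one per vertex.
#' @param algorithm optional character tag.
#' @param modularity optional modularity value recorded at selection.
#' @return A [Partition-class] object.
#' @examples
#' Partition(c("a", "a", "b", "a", "c"))
#' @export
Partition <- function(labels, algorithm = "user", modularity = NA_real_) {
  lab <- as.integer(factor(as.character(labels), levels = unique(as.character(labels)))) - 1L
  new("Partition", labels = lab, k = length(unique(lab)),
      algorithm = algorithm, modularity = as.numeric(modularity))
}

#' Planted partition of a ground-truth network
#'
#' @param net a [ModularNetwork-class].
#' @return The ground-truth module labels as a [Partition-class].
#' @export
plantedPartition <- function(net) {
  stopifnot(is(net, "ModularNetwork"))
  Partition(net@labels, algorithm = "planted")
}

setMethod("show", "ModularNetwork", function(object) {
  cat("ModularNetwork:", nrow(object@adjacency), "vertices,",
      sum(object@adjacency), "directed edges,",
      length(object@moduleSizes), "modules\n")
  cat("  module sizes:", paste(object@moduleSizes, collapse = " "), "\n")
  cat("  orientation: adjacency[i,j]=1 iff edge j->i\n")
})

setMethod("show", "ArCoefficients", function(object) {
  cat("ArCoefficients: order", object@order, "dimension",
      nrow(object@A[[1]]), "eta", object@eta, "\n")
})

setMethod("show", "MvarModel", function(object) {
  cat("MvarModel: K =", nrow(object@sigma), ", p =", object@p,
      ", residual columns =", ncol(object@residuals), "\n")
})

setMethod("show", "PcaReduction", function(object) {
  cat(sprintf("PcaReduction: C = %d of D = %d components (%.1f%% variance)\n",
              object@nComponents, ncol(object@W), 100 * object@varExplained))
})

setMethod("show", "ConnectivityMatrix", function(object) {
  cat(sprintf("ConnectivityMatrix (%s): D = %d, p = %d, C = %d (%.1f%% variance)\n",
              object@estimator, nrow(object@gamma), object@p, object@nComponents,
              100 * object@varExplained))
})

setMethod("show", "Partition", function(object) {
  cat("Partition:", length(object@labels), "vertices in", object@k,
      "modules [", object@algorithm, "]\n")
})
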