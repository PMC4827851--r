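# Generics and accessors.

#' Adjacency matrix of a network object
#'
#' @param x a [ModularNetwork-class], binary matrix, or igraph object.
#' @return Integer adjacency matrix with entry \code{[i, j] = 1} iff edge
#'   \code{j -> i}.
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' @describeIn adjacency planted-network adjacency.
#' @export
setMethod("adjacency", "ModularNetwork", function(x) x@adjacency)

#' Module labels of a network or partition
#'
#' @param x a [ModularNetwork-class] (planted 1-based labels) or a
#'   [Partition-class] (canonical 0-based labels).
#' @return Integer label vector.
#' @export
setGeneric("moduleLabels", function(x) standardGeneric("moduleLabels"))

#' @describeIn moduleLabels planted module ids (1-based).
#' @export
setMethod("moduleLabels", "ModularNetwork", function(x) x@labels)

#' @describeIn moduleLabels detected module ids (0-based, canonical).
#' @export
setMethod("moduleLabels", "Partition", function(x) x@labels)

#' Module sizes
#' @param x a [ModularNetwork-class].
#' @return Integer vector of planted module sizes.
#' @export
setGeneric("moduleSizes", function(x) standardGeneric("moduleSizes"))

#' @describeIn moduleSizes planted module sizes.
#' @export
setMethod("moduleSizes", "ModularNetwork", function(x) x@moduleSizes)

#' Number of vertices
#' @param x a network, partition or connectivity object.
#' @return Integer vertex count.
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))

#' @describeIn nVertices vertex count of the network.
#' @export
setMethod("nVertices", "ModularNetwork", function(x) nrow(x@adjacency))

#' @describeIn nVertices vertex count of the partition.
#' @export
setMethod("nVertices", "Partition", function(x) length(x@labels))

#' @describeIn nVertices dimension of the connectivity matrix.
#' @export
setMethod("nVertices", "ConnectivityMatrix", function(x) nrow(x@gamma))

#' Number of modules of a partition
#' @param x a [Partition-class].
#' @return Integer module count.
#' @export
setGeneric("nModules", function(x) standardGeneric("nModules"))

#' @describeIn nModules module count.
#' @export
setMethod("nModules", "Partition", function(x) x@k)

#' Coefficient matrices of an AR parameterization or fitted model
#' @param x an [ArCoefficients-class] or [MvarModel-class].
#' @return List of p square coefficient matrices.
#' @export
setGeneric("coefMatrices", function(x) standardGeneric("coefMatrices"))

#' @describeIn coefMatrices simulator coefficients.
#' @export
setMethod("coefMatrices", "ArCoefficients", function(x) x@A)

#' @describeIn coefMatrices fitted coefficients.
#' @export
setMethod("coefMatrices", "MvarModel", function(x) x@A)

#' Model order
#' @param x an [ArCoefficients-class] or [MvarModel-class].
#' @return Integer order p.
#' @export
setGeneric("modelOrder", function(x) standardGeneric("modelOrder"))

#' @describeIn modelOrder simulator order.
#' @export
setMethod("modelOrder", "ArCoefficients", function(x) x@order)

#' @describeIn modelOrder fitted order.
#' @export
setMethod("modelOrder", "MvarModel", function(x) x@p)

#' @describeIn fitMvar residuals of the fit (K-by-(N-p), rows = series).
#' @param object,... see \code{stats::residuals}.
#' @export
setMethod("residuals", "MvarModel", function(object, ...) object@residuals)

#' @describeIn fitMvar fitted values (K-by-(N-p), rows = series).
#' @export
setMethod("fitted", "MvarModel", function(object, ...) object@fitted)

#' Truncated mixing matrix of a PCA reduction
#' @param x a [PcaReduction-class].
#' @return The C-by-D matrix W with orthonormal rows.
#' @export
setGeneric("mixingMatrix", function(x) standardGeneric("mixingMatrix"))

#' @describeIn mixingMatrix the truncated mixing matrix.
#' @export
setMethod("mixingMatrix", "PcaReduction", function(x) x@W)

#' Eigenvalue spectrum of a PCA reduction
#' @param x a [PcaReduction-class].
#' @return All D eigenvalues, descending.
#' @export
setGeneric("eigenValues", function(x) standardGeneric("eigenValues"))

#' @describeIn eigenValues the eigenvalues.
#' @export
setMethod("eigenValues", "PcaReduction", function(x) x@eigenvalues)

#' Retained variance fraction
#' @param x a [PcaReduction-class] or [ConnectivityMatrix-class].
#' @return Cumulative eigenvalue fraction retained.
#' @export
setGeneric("varExplained", function(x) standardGeneric("varExplained"))

#' @describeIn varExplained variance retained by the reduction.
#' @export
setMethod("varExplained", "PcaReduction", function(x) x@varExplained)

#' @describeIn varExplained variance setting behind the connectivity matrix.
#' @export
setMethod("varExplained", "ConnectivityMatrix", function(x) x@varExplained)

#' Number of retained components
#' @param x a [PcaReduction-class] or [ConnectivityMatrix-class].
#' @return Integer C.
#' @export
setGeneric("retainedComponents", function(x) standardGeneric("retainedComponents"))

#' @describeIn retainedComponents components of the reduction.
#' @export
setMethod("retainedComponents", "PcaReduction", function(x) x@nComponents)

#' @describeIn retainedComponents components behind the connectivity matrix.
#' @export
setMethod("retainedComponents", "ConnectivityMatrix", function(x) x@nComponents)

#' Granger causality index matrix
#'
#' @param x a [ConnectivityMatrix-class].
#' @return D-by-D numeric matrix; entry \code{[j, i]} is the index from
#'   series i to series j; diagonal NA.
#' @export
setGeneric("gciValues", function(x) standardGeneric("gciValues"))

#' @describeIn gciValues the index matrix.
#' @export
setMethod("gciValues", "ConnectivityMatrix", function(x) x@gamma)

#' Estimator tag of a connectivity matrix
#' @param x a [ConnectivityMatrix-class].
#' @return \code{"gci"} or \code{"lsgc"}.
#' @export
setGeneric("estimatorTag", function(x) standardGeneric("estimatorTag"))

#' @describeIn estimatorTag the tag.
#' @export
setMethod("estimatorTag", "ConnectivityMatrix", function(x) x@estimator)
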