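# Plain-text interchange: TSV edge lists, dense matrices, partitions, time
# series with sidecar metadata. Every file carries a comment header naming
# the orientation convention so matrices cannot be silently transposed.

.orientationNote <- "# orientation: adjacency[i,j]=1 iff edge j->i; edge list columns are (source, target)"

#' Write / read a directed network as a TSV edge list
#'
#' Columns \code{source} and \code{target} (1-based vertex ids); a comment
#' header records the orientation convention and the vertex count so isolated
#' vertices survive the round trip.
#'
#' @param net binary adjacency matrix, [ModularNetwork-class] or igraph.
#' @param file path of the TSV file.
#' @return \code{writeEdgeList} returns the path invisibly;
#'   \code{readEdgeList} returns the adjacency matrix.
#' @export
writeEdgeList <- function(net, file) {
  A <- .asAdjacency(net)
  idx <- which(A == 1L, arr.ind = TRUE)
  df <- data.frame(source = idx[, "col"], target = idx[, "row"])
  df <- df[order(df$source, df$target), ]
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(.orientationNote, paste0("# vertices: ", nrow(A)),
               "source\ttarget"), con)
  if (nrow(df))
    writeLines(paste(df$source, df$target, sep = "\t"), con)
  invisible(file)
}

#' @rdname writeEdgeList
#' @export
readEdgeList <- function(file) {
  lines <- readLines(file)
  nv <- grep("^# vertices:", lines, value = TRUE)
  if (!length(nv)) stop("edge list ", file, " lacks the '# vertices:' header")
  D <- as.integer(sub("^# vertices:\\s*", "", nv[1]))
  df <- read.delim(file, comment.char = "#", header = TRUE)
  if (!all(c("source", "target") %in% names(df)))
    stop("edge list must have 'source' and 'target' columns")
  A <- matrix(0L, D, D)
  if (nrow(df)) A[cbind(df$target, df$source)] <- 1L
  A
}

#' Write / read a numeric matrix as dense TSV
#'
#' @param m numeric matrix (for connectivity matrices the NA diagonal is
#'   preserved).
#' @param file path.
#' @return \code{readMatrixTsv} returns the matrix.
#' @export
writeMatrixTsv <- function(m, file) {
  write.table(m, file, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' @rdname writeMatrixTsv
#' @export
readMatrixTsv <- function(file) {
  df <- tryCatch(read.delim(file, header = FALSE, comment.char = "#"),
                 error = function(e) stop("cannot parse ", file, ": ",
                                          conditionMessage(e)))
  m <- as.matrix(df)
  if (!is.numeric(m))
    stop("non-numeric entries in ", file, " (first offending column: ",
         which(!vapply(df, is.numeric, logical(1)))[1], ")")
  dimnames(m) <- NULL
  m
}

#' Write / read a time-series matrix with sidecar metadata
#'
#' The series matrix (rows = series) is stored as dense TSV; a sidecar file
#' \code{<file>.meta.tsv} records D, N and any supplied metadata (p, seed).
#'
#' @param y D-by-N numeric matrix.
#' @param file path of the TSV file.
#' @param meta named list of additional metadata values.
#' @return \code{readTimeSeries} returns the matrix with the metadata in
#'   \code{attr(, "meta")} when the sidecar is present.
#' @export
writeTimeSeries <- function(y, file, meta = list()) {
  writeMatrixTsv(y, file)
  meta <- c(list(D = nrow(y), N = ncol(y)), meta)
  write.table(data.frame(key = names(meta),
                         value = vapply(meta, as.character, character(1))),
              paste0(file, ".meta.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname writeTimeSeries
#' @export
readTimeSeries <- function(file) {
  y <- readMatrixTsv(file)
  metaFile <- paste0(file, ".meta.tsv")
  if (file.exists(metaFile)) {
    df <- read.delim(metaFile)
    attr(y, "meta") <- stats::setNames(as.list(df$value), df$key)
  }
  y
}

#' Write / read a partition as two-column TSV
#'
#' Columns \code{vertex_id} (1-based) and \code{module_id} (0-based canonical
#' labels).
#'
#' @param partition a [Partition-class] or label vector.
#' @param file path.
#' @return \code{readPartition} returns a [Partition-class].
#' @export
writePartition <- function(partition, file) {
  lab <- .labelsOf(partition)
  write.table(data.frame(vertex_id = seq_along(lab), module_id = lab),
              file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname writePartition
#' @export
readPartition <- function(file) {
  df <- read.delim(file)
  if (!all(c("vertex_id", "module_id") %in% names(df)))
    stop("partition file must have 'vertex_id' and 'module_id' columns")
  Partition(df$module_id[order(df$vertex_id)])
}

#' Write a connectivity matrix with a descriptive header
#'
#' Dense TSV preceded by comment lines recording the estimator tag, model
#' order, retained components, variance explained and the
#' target-row/source-column orientation.
#'
#' @param cm a [ConnectivityMatrix-class].
#' @param file path.
#' @return The path, invisibly.
#' @export
writeConnectivity <- function(cm, file) {
  stopifnot(is(cm, "ConnectivityMatrix"))
  con <- file(file, "w")
  writeLines(c("# orientation: gamma[j,i] = index from series i to series j",
               sprintf("# estimator: %s", cm@estimator),
               sprintf("# p: %d", cm@p),
               sprintf("# C: %d", cm@nComponents),
               sprintf("# varExplained: %.10g", cm@varExplained)), con)
  close(con)
  suppressWarnings(write.table(cm@gamma, file, sep = "\t", row.names = FALSE,
                               col.names = FALSE, append = TRUE))
  invisible(file)
}
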