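# Internal helpers: deterministic seed derivation, RNG scoping, coercions.

# Derive a reproducible 31-bit sub-seed from (seed, label, index). A small
# multiplicative mix keeps all arithmetic exact in doubles (< 2^53) and the
# result below 2^31 - 1.
.deriveSeed <- function(seed, what, index = 0L) {
  m <- 2147483647 # 2^31 - 1
  h <- (as.numeric(seed) %% m + 1)
  bytes <- c(utf8ToInt(what), as.numeric(index) %% m)
  for (b in bytes) h <- (h * 48271 + b + 1) %% m
  as.integer(max(1, h))
}

# Evaluate expr under a fixed seed without disturbing the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Coerce networks (ModularNetwork / binary matrix / igraph) to the package
# adjacency convention A[i, j] = 1 iff edge j -> i. igraph stores A[i, j] for
# i -> j, hence the transpose.
.asAdjacency <- function(x) {
  if (is(x, "ModularNetwork")) return(x@adjacency)
  if (inherits(x, "igraph")) {
    A <- as.matrix(igraph::as_adjacency_matrix(x, sparse = FALSE))
    return(t((A > 0) + 0L))
  }
  if (is.matrix(x)) {
    if (nrow(x) != ncol(x)) stop("adjacency matrix must be square")
    storage.mode(x) <- "integer"
    return(x)
  }
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as a directed network")
}

# igraph view of a package-convention adjacency matrix.
.asGraph <- function(adj, mode = c("directed", "undirected")) {
  mode <- match.arg(mode)
  igraph::graph_from_adjacency_matrix(t(adj), mode = mode)
}

.asGamma <- function(x) {
  if (is(x, "ConnectivityMatrix")) return(x@gamma)
  if (is.matrix(x)) return(x)
  stop("expected a ConnectivityMatrix or a numeric matrix")
}

.offDiagonal <- function(m) m[row(m) != col(m)]

# Canonical 0-based integer labels from a Partition or any label vector.
.labelsOf <- function(x) {
  if (is(x, "Partition")) return(x@labels)
  if (is(x, "ModularNetwork")) return(x@labels - 1L)
  as.integer(factor(as.character(x), levels = unique(as.character(x)))) - 1L
}

.centerRows <- function(y) y - rowMeans(y)
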