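# Partition quality and partition similarity measures. All measures are
# invariant under module relabelling; information measures use the natural
# logarithm.

.checkSameVertices <- function(a, b) {
  if (length(a) != length(b))
    stop("partitions are defined over different vertex sets (lengths ",
         length(a), " and ", length(b), ")")
}

.contingency <- function(a, b) table(factor(a), factor(b))

#' Pair classification counts of two partitions
#'
#' Classifies every unordered vertex pair by whether its two vertices share a
#' module in partition A and in partition B: \code{N11} together in both,
#' \code{N00} apart in both, \code{N01} apart in A / together in B, \code{N10}
#' together in A / apart in B. The four counts sum to \code{D*(D-1)/2}.
#'
#' @param pa,pb [Partition-class] objects (or label vectors) over the same
#'   vertex set.
#' @return Named integer-valued vector with elements N11, N00, N01, N10.
#' @examples
#' pairCounts(c(1, 1, 2), c(1, 2, 2)) # (0, 1, 1, 1)
#' @export
pairCounts <- function(pa, pb) {
  a <- .labelsOf(pa); b <- .labelsOf(pb)
  .checkSameVertices(a, b)
  n <- length(a)
  tab <- .contingency(a, b)
  nij2 <- sum(choose(tab, 2))
  ai2 <- sum(choose(rowSums(tab), 2))
  bj2 <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  c(N11 = nij2, N00 = total - ai2 - bj2 + nij2,
    N01 = bj2 - nij2, N10 = ai2 - nij2)
}

#' Rand index
#'
#' Fraction of vertex pairs classified concordantly by the two partitions,
#' \code{(N11 + N00) / (N11 + N00 + N01 + N10)}.
#'
#' @inheritParams pairCounts
#' @return Value in [0, 1]; 1 iff the partitions coincide.
#' @export
randIndex <- function(pa, pb) {
  pc <- pairCounts(pa, pb)
  unname((pc["N11"] + pc["N00"]) / sum(pc))
}

#' Adjusted Rand index
#'
#' Hubert-Arabie chance-corrected Rand index: 1 for identical partitions,
#' expectation approximately 0 for independent random partitions.
#'
#' @inheritParams pairCounts
#' @return Chance-corrected index (can be negative).
#' @export
adjustedRand <- function(pa, pb) {
  a <- .labelsOf(pa); b <- .labelsOf(pb)
  .checkSameVertices(a, b)
  tab <- .contingency(a, b)
  n <- length(a)
  nij2 <- sum(choose(tab, 2))
  ai2 <- sum(choose(rowSums(tab), 2))
  bj2 <- sum(choose(colSums(tab), 2))
  expect <- ai2 * bj2 / choose(n, 2)
  maxi <- (ai2 + bj2) / 2
  if (maxi == expect) return(1) # both partitions trivial
  (nij2 - expect) / (maxi - expect)
}

#' Mutual information of two partitions
#'
#' Mutual information of the module-label contingency table, in nats. Equals
#' the entropy of either partition when the two coincide, and 0 when either
#' partition has a single module.
#'
#' @inheritParams pairCounts
#' @return Nonnegative value in nats.
#' @export
mutualInformation <- function(pa, pb) {
  a <- .labelsOf(pa); b <- .labelsOf(pb)
  .checkSameVertices(a, b)
  p <- .contingency(a, b) / length(a)
  pi <- rowSums(p); pj <- colSums(p)
  idx <- p > 0
  sum(p[idx] * log(p[idx] / outer(pi, pj)[idx]))
}

.entropy <- function(lab) {
  p <- tabulate(lab + 1L) / length(lab)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Variation of information
#'
#' \code{VI = H(A) + H(B) - 2 MI(A, B)} in nats; a metric on the space of
#' partitions of a fixed vertex set (zero iff the partitions coincide).
#'
#' @inheritParams pairCounts
#' @return Nonnegative value in nats.
#' @export
variationOfInformation <- function(pa, pb) {
  a <- .labelsOf(pa); b <- .labelsOf(pb)
  .checkSameVertices(a, b)
  vi <- .entropy(a) + .entropy(b) - 2 * mutualInformation(a, b)
  max(vi, 0)
}

#' Split-join (van Dongen) distance
#'
#' Measures the extent to which two partitions are subpartitions of each
#' other: \code{d = (n - sum_A max-overlap) + (n - sum_B max-overlap)},
#' an integer bounded by 2n, zero iff the partitions coincide.
#'
#' @inheritParams pairCounts
#' @return Nonnegative integer.
#' @export
splitJoinDistance <- function(pa, pb) {
  a <- .labelsOf(pa); b <- .labelsOf(pb)
  .checkSameVertices(a, b)
  tab <- .contingency(a, b)
  n <- length(a)
  as.integer((n - sum(apply(tab, 1, max))) + (n - sum(apply(tab, 2, max))))
}

# ---- Jaccard-cost assignment matching ----------------------------------

# O(n^3) shortest-augmenting-path (Jonker-Volgenant style) solver for the
# square assignment problem with potentials u, v and per-column predecessors
# 'way'; column n+1 plays the role of the virtual start column. Returns the
# column assigned to each row.
.hungarian <- function(cost) {
  n <- nrow(cost)
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[n + 1] <- i
    j0 <- n + 1L
    minv <- rep(INF, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- INF
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(n + 1)) {
        if (used[j]) {
          u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == n + 1L) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(n)) if (p[j] > 0L) assign[p[j]] <- j
  assign
}

#' Match modules of two partitions by Jaccard-cost assignment
#'
#' Builds the cost matrix of Jaccard distances (1 - |intersection| / |union|
#' of vertex sets) between every module of partition A and every module of
#' partition B and solves the resulting (rectangular) assignment problem
#' optimally. Surplus modules of the larger partition remain unmatched.
#'
#' @inheritParams pairCounts
#' @return List with \code{mapping} (integer vector over A's modules, 0-based
#'   ids; entry = matched B module id or NA), \code{cost} (total Jaccard
#'   distance over matched pairs) and \code{costMatrix}.
#' @export
matchModules <- function(pa, pb) {
  a <- .labelsOf(pa); b <- .labelsOf(pb)
  .checkSameVertices(a, b)
  ka <- max(a) + 1L; kb <- max(b) + 1L
  tab <- matrix(0L, ka, kb)
  tt <- .contingency(a, b)
  tab[cbind(as.integer(rownames(tt))[row(tt)] + 1L,
            as.integer(colnames(tt))[col(tt)] + 1L)] <- as.integer(tt)
  sa <- rowSums(tab); sb <- colSums(tab)
  jac <- 1 - tab / (outer(sa, sb, "+") - tab)
  n <- max(ka, kb)
  cost <- matrix(1, n, n) # unmatched == Jaccard distance 1
  cost[seq_len(ka), seq_len(kb)] <- jac
  assign <- .hungarian(cost)
  mapping <- rep(NA_integer_, ka)
  for (i in seq_len(ka)) {
    j <- assign[i]
    if (j <= kb && jac[i, j] < 1) mapping[i] <- j - 1L
  }
  matched <- which(!is.na(mapping))
  list(mapping = mapping,
       cost = sum(jac[cbind(matched, mapping[matched] + 1L)]),
       costMatrix = jac)
}

#' Ratio of correctly classified vertices
#'
#' Matches the modules of the two partitions by the Jaccard-cost assignment
#' of [matchModules()] and counts the vertices that lie in a matched module
#' pair in both partitions; vertices of unmatched modules count as
#' misclassified.
#'
#' @param pa reference partition (e.g. the planted ground truth).
#' @param pb detected partition.
#' @return Fraction in [0, 1]; 1 iff the matching maps the partitions onto
#'   each other exactly.
#' @export
correctClassifiedRatio <- function(pa, pb) {
  a <- .labelsOf(pa); b <- .labelsOf(pb)
  .checkSameVertices(a, b)
  mm <- matchModules(a, b)
  correct <- 0L
  for (i in seq_along(mm$mapping)) {
    j <- mm$mapping[i]
    if (!is.na(j)) correct <- correct + sum(a == (i - 1L) & b == j)
  }
  correct / length(a)
}

#' Coverage of a partitioned network
#'
#' Ratio of intra-module directed edges to all directed edges. Equals 1 when
#' no inter-module edges exist (e.g. under a single-module partition).
#'
#' @param net a binary adjacency matrix, [ModularNetwork-class] or igraph.
#' @param partition a [Partition-class] or label vector.
#' @return Fraction in [0, 1].
#' @export
coverage <- function(net, partition) {
  A <- .asAdjacency(net)
  lab <- .labelsOf(partition)
  if (length(lab) != nrow(A)) stop("partition length must equal vertex count")
  m <- sum(A)
  if (m == 0) stop("network has no edges; coverage undefined")
  same <- outer(lab, lab, "==")
  sum(A[same]) / m
}

#' Performance of a partitioned network
#'
#' Fraction of correctly "interpreted" unordered vertex pairs: pairs in the
#' same module that interact (at least one arc in either direction) plus
#' pairs in different modules that do not, over all \code{D*(D-1)/2} pairs.
#'
#' @inheritParams coverage
#' @return Fraction in [0, 1].
#' @export
partitionPerformance <- function(net, partition) {
  A <- .asAdjacency(net)
  lab <- .labelsOf(partition)
  if (length(lab) != nrow(A)) stop("partition length must equal vertex count")
  E <- symmetrizeNetwork(A)
  same <- outer(lab, lab, "==")
  up <- upper.tri(E)
  (sum(E[up] == 1L & same[up]) + sum(E[up] == 0L & !same[up])) / sum(up)
}

#' Modularity of a partitioned network
#'
#' Newman-Girvan modularity on the symmetrized network
#' (\code{directed = FALSE}) or Leicht-Newman directed modularity with the
#' in/out-degree null model (\code{directed = TRUE}). A single-module
#' partition scores 0 in both variants, and the directed variant reduces to
#' the undirected one on symmetric adjacency matrices.
#'
#' @inheritParams coverage
#' @param directed use the directed (Leicht-Newman) null model.
#' @return Modularity value (at most 1; can be negative).
#' @export
networkModularity <- function(net, partition, directed = TRUE) {
  A <- .asAdjacency(net)
  lab <- .labelsOf(partition)
  if (length(lab) != nrow(A)) stop("partition length must equal vertex count")
  if (directed) {
    .directedModularityS(t(A), lab)
  } else {
    E <- symmetrizeNetwork(A)
    m2 <- sum(E) # = 2m
    if (m2 == 0) return(0)
    deg <- rowSums(E)
    q <- 0
    for (c in unique(lab)) {
      idx <- which(lab == c)
      q <- q + sum(E[idx, idx]) / m2 - (sum(deg[idx]) / m2)^2
    }
    q
  }
}

#' Partition edit distance of intra-module edge patterns
#'
#' For every matched module pair (Jaccard-cost assignment), the intra-module
#' adjacency submatrices of the two networks are aligned on the union of the
#' two vertex sets (vertices absent from a module padded as zero rows and
#' columns), vectorized row-major to binary strings, and compared by the
#' Levenshtein edit distance; the distances are summed over matched pairs.
#'
#' @param netA,netB binary adjacency matrices (or [ModularNetwork-class] /
#'   igraph) on the same vertex set.
#' @param pa,pb the corresponding partitions.
#' @param matching optional precomputed result of \code{matchModules(pa, pb)}.
#' @return Nonnegative integer.
#' @export
partitionEditDistance <- function(netA, netB, pa, pb, matching = NULL) {
  A <- .asAdjacency(netA); B <- .asAdjacency(netB)
  a <- .labelsOf(pa); b <- .labelsOf(pb)
  .checkSameVertices(a, b)
  if (!all(dim(A) == dim(B))) stop("networks must share the vertex set")
  if (is.null(matching)) matching <- matchModules(a, b)
  total <- 0L
  for (i in seq_along(matching$mapping)) {
    j <- matching$mapping[i]
    if (is.na(j)) next
    va <- which(a == (i - 1L)); vb <- which(b == j)
    u <- sort(union(va, vb))
    subA <- A[u, u, drop = FALSE]
    subA[!(u %in% va), ] <- 0L; subA[, !(u %in% va)] <- 0L
    subB <- B[u, u, drop = FALSE]
    subB[!(u %in% vb), ] <- 0L; subB[, !(u %in% vb)] <- 0L
    sA <- paste(as.vector(t(subA)), collapse = "")
    sB <- paste(as.vector(t(subB)), collapse = "")
    total <- total + as.integer(adist(sA, sB))
  }
  total
}
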