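# Uniform interface to the module-detection algorithms, with symmetrization
# for undirected algorithms and highest-modularity partition selection.
# Undirected algorithms are thin adapters over igraph; the two directed
# variants (Leicht-Newman leading eigenvector, directed-modularity Louvain)
# are implemented here because igraph provides no directed counterpart.

#' Symmetrize a directed binary network
#'
#' Replaces every directed edge by an undirected one: an undirected edge
#' \{i, j\} exists iff i->j or j->i exists.
#'
#' @param net a binary adjacency matrix, [ModularNetwork-class] or igraph.
#' @return Symmetric binary matrix.
#' @export
symmetrizeNetwork <- function(net) {
  A <- .asAdjacency(net)
  ((A + t(A)) > 0L) + 0L
}

# ---- directed modularity machinery (Leicht-Newman null model) ----------

# Q = (1/m) * sum_c [ w_c - KoutC * KinC / m ] for a weighted directed graph
# given in source->target orientation S[i, j] = weight of arc i -> j.
.directedModularityS <- function(S, lab) {
  m <- sum(S)
  if (m == 0) return(0)
  kout <- rowSums(S); kin <- colSums(S)
  q <- 0
  for (c in unique(lab)) {
    idx <- which(lab == c)
    q <- q + sum(S[idx, idx]) / m -
      sum(kout[idx]) * sum(kin[idx]) / m^2
  }
  q
}

# Louvain-style greedy optimization of Leicht-Newman directed modularity:
# sweeps of single-vertex moves to the neighbouring community with the best
# gain, followed by community aggregation, repeated until no gain. S is the
# weighted source->target matrix (self-loops arise from aggregation).
.louvainDirected <- function(S) {
  n0 <- nrow(S)
  membership <- seq_len(n0)
  repeat {
    n <- nrow(S)
    m <- sum(S)
    if (m == 0) break
    kout <- rowSums(S); kin <- colSums(S)
    comm <- seq_len(n)
    improvedLevel <- FALSE
    repeat {
      moved <- FALSE
      for (i in sample.int(n)) {
        ci <- comm[i]
        neigh <- unique(comm[c(which(S[i, ] > 0), which(S[, i] > 0))])
        neigh <- setdiff(neigh, ci)
        if (!length(neigh)) next
        comm_i <- comm
        comm_i[i] <- 0L # take i out of its community
        # gain of joining community d (relative to staying alone)
        gains <- vapply(neigh, function(d) {
          idx <- which(comm_i == d)
          (sum(S[i, idx]) + sum(S[idx, i])) / m -
            (kout[i] * sum(kin[idx]) + kin[i] * sum(kout[idx])) / m^2
        }, numeric(1))
        idxC <- which(comm_i == ci)
        gainStay <- if (length(idxC))
          (sum(S[i, idxC]) + sum(S[idxC, i])) / m -
            (kout[i] * sum(kin[idxC]) + kin[i] * sum(kout[idxC])) / m^2
        else 0
        best <- which.max(gains)
        if (gains[best] > gainStay + 1e-12) {
          comm[i] <- neigh[best]
          moved <- TRUE
          improvedLevel <- TRUE
        }
      }
      if (!moved) break
    }
    if (!improvedLevel) break
    # aggregate
    comm <- as.integer(factor(comm))
    k <- max(comm)
    membership <- comm[membership]
    if (k == n) break
    M <- matrix(0, n, k)
    M[cbind(seq_len(n), comm)] <- 1
    S <- t(M) %*% S %*% M
    if (k == 1L) break
  }
  membership
}

# Kernighan-Lin style fine-tuning of a spectral bisection (the refinement
# stage of the canonical leading-eigenvector algorithm): every vertex is
# moved exactly once per sweep in order of best gain of the modularity
# quadratic form q(s) = s' Bg s, the best intermediate configuration is kept,
# and sweeps repeat while q improves.
.klRefine <- function(Bg, s, maxSweeps = 30L) {
  n <- length(s)
  tol <- 1e-9 * (1 + sum(abs(Bg)) / n) # above the incremental-update drift
  qOf <- function(v) sum(v * (Bg %*% v))
  qBase <- qOf(s)
  for (sweep in seq_len(maxSweeps)) {
    moved <- rep(FALSE, n)
    g <- as.vector(Bg %*% s)
    q <- qBase
    bestQ <- qBase; bestS <- s
    sCur <- s
    for (step in seq_len(n)) {
      gains <- -4 * sCur * g + 4 * diag(Bg)
      gains[moved] <- -Inf
      i <- which.max(gains)
      q <- q + gains[i]
      g <- g - 2 * sCur[i] * Bg[, i]
      sCur[i] <- -sCur[i]
      moved[i] <- TRUE
      if (q > bestQ + tol) { bestQ <- q; bestS <- sCur }
    }
    # accept the sweep only on a genuine (recomputed) improvement
    qNew <- qOf(bestS)
    if (qNew <= qBase + tol) break
    s <- bestS
    qBase <- qNew
  }
  s
}

# Leicht-Newman leading-eigenvector community detection: recursive spectral
# bisection of the (symmetrized) directed modularity matrix with
# Kernighan-Lin fine-tuning after every split, stopping when a split no
# longer increases modularity. On a symmetric adjacency this reduces to
# Newman's undirected leading-eigenvector algorithm.
.leadingEigenDirected <- function(S) {
  n <- nrow(S)
  m <- sum(S)
  if (m == 0) return(rep(1L, n))
  kout <- rowSums(S); kin <- colSums(S)
  B <- S - outer(kout, kin) / m
  M <- (B + t(B)) / 2
  lab <- rep(1L, n)
  nextId <- 2L
  queue <- list(seq_len(n))
  while (length(queue)) {
    g <- queue[[1]]; queue <- queue[-1]
    if (length(g) < 2L) next
    Bg <- M[g, g, drop = FALSE]
    diag(Bg) <- diag(Bg) - rowSums(Bg)
    ev <- eigen(Bg, symmetric = TRUE)
    if (ev$values[1] <= 1e-10) next
    s <- sign(ev$vectors[, 1])
    s[s == 0] <- 1
    s <- .klRefine(Bg, s)
    dQ <- as.numeric(t(s) %*% Bg %*% s)
    if (dQ <= 1e-10 || all(s == s[1])) next
    g2 <- g[s < 0]
    lab[g2] <- nextId
    nextId <- nextId + 1L
    queue <- c(queue, list(g[s > 0]), list(g2))
  }
  as.integer(factor(lab))
}

#' Detect network modules
#'
#' Uniform adapter over seven community detection algorithms. Algorithms
#' designed for undirected networks (\code{walktrap}, \code{fast_greedy},
#' \code{leading_eigenvector}, \code{spinglass}, \code{louvain}) receive the
#' symmetrized network in its multiplicity-preserving form \code{A + t(A)}
#' (each directed edge becomes an undirected one, so reciprocated pairs carry
#' weight 2); \code{leading_eigenvector_directed} (Leicht-Newman)
#' and \code{louvain_directed} (greedy local moves scoring Leicht-Newman
#' directed modularity) work on the directed adjacency. When an algorithm
#' explores a hierarchy of partitions, the level with maximal modularity is
#' returned. Stochastic algorithms take an explicit seed and are reproducible
#' under it. \code{infomap} is also wired in, but is not part of the default
#' benchmark set.
#'
#' @param net a binary adjacency matrix, [ModularNetwork-class] or igraph
#'   (orientation \code{A[i, j] = 1} iff edge \code{j -> i}).
#' @param algorithm one of \code{"leading_eigenvector_directed"},
#'   \code{"louvain_directed"}, \code{"walktrap"}, \code{"fast_greedy"},
#'   \code{"leading_eigenvector"}, \code{"spinglass"}, \code{"louvain"},
#'   \code{"infomap"}.
#' @param seed integer seed for stochastic algorithms.
#' @return A [Partition-class]; its \code{modularity} slot records the
#'   (directed or undirected, matching the algorithm class) modularity of the
#'   selected partition.
#' @examples
#' A <- matrix(0L, 20, 20)
#' A[1:10, 1:10] <- 1L; A[11:20, 11:20] <- 1L; diag(A) <- 0L
#' A[1, 11] <- 1L
#' nModules(detectModules(A, "louvain", seed = 1)) # 2 planted cliques
#' @export
detectModules <- function(net,
                          algorithm = c("leading_eigenvector_directed",
                                        "louvain_directed", "walktrap",
                                        "fast_greedy", "leading_eigenvector",
                                        "spinglass", "louvain", "infomap"),
                          seed = 1L) {
  algorithm <- match.arg(algorithm)
  A <- .asAdjacency(net)
  directedAlg <- algorithm %in% c("leading_eigenvector_directed",
                                  "louvain_directed", "infomap")
  if (algorithm == "spinglass" && !checkConnectedness(A))
    stop("spinglass requires a connected network; input is disconnected")
  S <- t(A) # source -> target orientation for the directed machinery
  # Undirected algorithms receive the multiplicity-preserving symmetrization
  # A + t(A): every directed edge becomes an undirected one, so a
  # reciprocated pair carries weight 2. Keeping the reciprocity information
  # is what lets agglomerative detectors separate modules whose internal
  # edges are far more often reciprocated than their external ones.
  Wsym <- A + t(A)
  gU <- function() igraph::graph_from_adjacency_matrix(Wsym,
    mode = "undirected", weighted = TRUE)
  lab <- .withSeed(.deriveSeed(seed, paste0("detect-", algorithm)), {
    switch(algorithm,
      leading_eigenvector_directed = .leadingEigenDirected(S),
      louvain_directed = .louvainDirected(S),
      walktrap =
        as.integer(igraph::membership(igraph::cluster_walktrap(gU()))),
      fast_greedy =
        as.integer(igraph::membership(igraph::cluster_fast_greedy(gU()))),
      leading_eigenvector =
        # Newman's undirected algorithm = the directed machinery on the
        # symmetric matrix (includes the canonical fine-tuning stage,
        # which igraph's cluster_leading_eigen omits)
        .leadingEigenDirected(Wsym),
      spinglass =
        as.integer(igraph::membership(igraph::cluster_spinglass(gU()))),
      louvain =
        as.integer(igraph::membership(igraph::cluster_louvain(gU()))),
      infomap = {
        g <- .asGraph(A, "directed")
        as.integer(igraph::membership(igraph::cluster_infomap(g)))
      })
  })
  part <- Partition(lab, algorithm = algorithm)
  part@modularity <- networkModularity(A, part, directed = directedAlg)
  part
}
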