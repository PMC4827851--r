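# Partition quality and similarity measures.

test_that("pair counts classify every unordered vertex pair", {
  pc <- pairCounts(c(1, 1, 2), c(1, 2, 2))
  expect_equal(unname(pc), c(0, 1, 1, 1)) # enumerate the 3 pairs by hand
  expect_equal(sum(pc), choose(3, 2))
  ident <- pairCounts(c(1, 2, 2, 3), c(1, 2, 2, 3))
  expect_equal(unname(ident[c("N01", "N10")]), c(0, 0))
  singl <- pairCounts(1:6, 1:6)
  expect_equal(unname(singl["N00"]), choose(6, 2))
  expect_error(pairCounts(1:3, 1:4), "vertex")
})

test_that("Rand index reproduces closed forms and is symmetric", {
  expect_equal(randIndex(c(1, 1, 2), c(1, 2, 2)), 1 / 3)
  expect_equal(randIndex(c(1, 2, 2), c(5, 9, 9)), 1) # label invariance
  set.seed(91)
  a <- sample(1:4, 30, TRUE); b <- sample(1:3, 30, TRUE)
  expect_equal(randIndex(a, b), randIndex(b, a))
  expect_true(randIndex(a, b) >= 0 && randIndex(a, b) <= 1)
})

test_that("adjusted Rand matches mclust and its closed form", {
  a6 <- c(1, 1, 2, 2, 3, 3); b6 <- c(1, 1, 1, 2, 2, 3)
  # direct Hubert-Arabie evaluation from the contingency table
  tab <- table(a6, b6)
  nij2 <- sum(choose(tab, 2)); ai2 <- sum(choose(rowSums(tab), 2))
  bj2 <- sum(choose(colSums(tab), 2)); ex <- ai2 * bj2 / choose(6, 2)
  oracle <- (nij2 - ex) / ((ai2 + bj2) / 2 - ex)
  expect_equal(adjustedRand(a6, b6), oracle, tolerance = 1e-12)
  expect_equal(adjustedRand(a6, a6), 1)
  skip_if_not_installed("mclust")
  set.seed(92)
  for (r in 1:5) {
    a <- sample(1:5, 40, TRUE); b <- sample(1:4, 40, TRUE)
    expect_equal(adjustedRand(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
})

test_that("independent random partitions have near-zero expected ARI", {
  set.seed(93)
  vals <- replicate(200, adjustedRand(sample(1:4, 24, TRUE),
                                      sample(1:4, 24, TRUE)))
  expect_lt(abs(mean(vals)), 0.02)
})

test_that("information measures obey their identities", {
  set.seed(94)
  a <- sample(1:4, 50, TRUE)
  expect_equal(mutualInformation(a, a), lsgc:::.entropy(lsgc:::.labelsOf(a)),
               tolerance = 1e-12)
  expect_equal(variationOfInformation(a, a), 0)
  expect_equal(mutualInformation(a, rep(1, 50)), 0) # single module: MI = 0
  b <- sample(1:3, 50, TRUE)
  expect_equal(mutualInformation(a, b), mutualInformation(b, a), tolerance = 1e-12)
  expect_equal(variationOfInformation(a, b), variationOfInformation(b, a),
               tolerance = 1e-12)
})

test_that("variation of information satisfies the triangle inequality", {
  set.seed(95)
  for (r in 1:25) {
    a <- sample(1:4, 20, TRUE); b <- sample(1:4, 20, TRUE); c <- sample(1:4, 20, TRUE)
    expect_lte(variationOfInformation(a, c),
               variationOfInformation(a, b) + variationOfInformation(b, c) + 1e-12)
  }
})

test_that("split-join distance matches an exhaustive overlap oracle", {
  expect_identical(splitJoinDistance(1:5, 1:5), 0L)
  # one 10-vertex module split 5/5, 90 other vertices identical
  a <- c(rep(1, 10), rep(2:10, each = 10))
  b <- c(rep(1, 5), rep(99, 5), rep(2:10, each = 10))
  overlap <- function(x, y) {
    s <- 0
    for (u in unique(x)) s <- s + max(table(y[x == u]))
    length(x) - s
  }
  expect_identical(splitJoinDistance(a, b),
                   as.integer(overlap(a, b) + overlap(b, a)))
  expect_identical(splitJoinDistance(a, b), 5L) # the smaller split part
  set.seed(96)
  for (r in 1:10) {
    x <- sample(1:5, 30, TRUE); y <- sample(1:6, 30, TRUE)
    d <- splitJoinDistance(x, y)
    expect_identical(d, as.integer(overlap(x, y) + overlap(y, x)))
    expect_lte(d, 2L * 30L)
    expect_identical(d, splitJoinDistance(y, x))
  }
})

test_that("the assignment solver is optimal against brute force", {
  set.seed(97)
  for (r in 1:20) {
    n <- sample(2:6, 1)
    cost <- matrix(runif(n * n), n, n)
    assign <- lsgc:::.hungarian(cost)
    expect_identical(sort(assign), 1:n) # a permutation
    expect_equal(sum(cost[cbind(1:n, assign)]), brute_assignment_cost(cost),
                 tolerance = 1e-12)
  }
})

test_that("module matching and correct-ratio follow the Jaccard assignment", {
  a <- rep(1:3, each = 4)
  mm <- matchModules(a, a)
  expect_identical(mm$mapping, 0:2) # identity matching
  expect_equal(mm$cost, 0)
  expect_equal(correctClassifiedRatio(a, a), 1)
  # one 10-vertex module of A split 5/5 in B, rest identical (D = 100):
  # one half is unmatched, so the ratio drops to 0.95
  pa <- c(rep(1, 10), rep(2:10, each = 10))
  pb <- c(rep(1, 5), rep(99, 5), rep(2:10, each = 10))
  expect_equal(correctClassifiedRatio(pa, pb), 0.95)
  # label-permutation invariance
  set.seed(98)
  x <- sample(1:5, 60, TRUE); y <- sample(1:4, 60, TRUE)
  perm <- sample(1:5)
  expect_equal(correctClassifiedRatio(x, y),
               correctClassifiedRatio(perm[x], y))
  expect_lte(correctClassifiedRatio(x, y), 1)
})

test_that("coverage counts directed intra-module edges", {
  # 10 directed edges, 7 intra under the given labels
  A <- matrix(0L, 6, 6)
  intra <- rbind(c(2, 1), c(3, 1), c(1, 2), c(3, 2), c(5, 4), c(4, 5), c(6, 5))
  inter <- rbind(c(4, 1), c(5, 2), c(1, 6))
  A[intra] <- 1L; A[inter] <- 1L
  lab <- c(1, 1, 1, 2, 2, 2)
  expect_equal(coverage(A, lab), 0.7)
  expect_equal(coverage(A, rep(1, 6)), 1) # single module
  net <- generateGroundTruthNetwork(100, seed = 99)
  # Partition objects and raw label vectors are interchangeable
  expect_equal(coverage(net, plantedPartition(net)),
               coverage(net, moduleLabels(net)))
})

test_that("performance equals an exhaustive pair audit", {
  set.seed(100)
  A <- matrix(rbinom(25, 1, 0.4), 5, 5); diag(A) <- 0L
  lab <- c(1, 1, 2, 2, 2)
  und <- (A + t(A)) > 0
  good <- 0
  for (i in 1:4) for (j in (i + 1):5)
    good <- good + ((lab[i] == lab[j]) == und[i, j])
  expect_equal(partitionPerformance(A, lab), good / 10)
  # disjoint cliques with the matching partition: performance 1
  cl <- matrix(0L, 6, 6); cl[1:3, 1:3] <- 1L; cl[4:6, 4:6] <- 1L; diag(cl) <- 0L
  expect_equal(partitionPerformance(cl, c(1, 1, 1, 2, 2, 2)), 1)
  # single-module partition on a sparse net scores the edge density
  expect_equal(partitionPerformance(A, rep(1, 5)), sum(und[upper.tri(und)]) / 10)
})

test_that("modularity reproduces closed forms and the igraph reference", {
  # two disjoint 5-cliques, 2-module partition: undirected Q = 0.5
  cl <- matrix(0L, 10, 10); cl[1:5, 1:5] <- 1L; cl[6:10, 6:10] <- 1L; diag(cl) <- 0L
  lab <- rep(1:2, each = 5)
  expect_equal(networkModularity(cl, lab, directed = FALSE), 0.5)
  expect_equal(networkModularity(cl, rep(1, 10), directed = FALSE), 0) # single module
  expect_equal(networkModularity(cl, rep(1, 10), directed = TRUE), 0)
  # directed variant equals the undirected value on symmetric networks
  expect_equal(networkModularity(cl, lab, directed = TRUE),
               networkModularity(cl, lab, directed = FALSE), tolerance = 1e-12)
  # igraph as independent reference on a random symmetric network
  set.seed(101)
  R <- symmetrizeNetwork(matrix(rbinom(144, 1, 0.3), 12, 12) * upper.tri(diag(12)))
  labR <- sample(1:3, 12, TRUE)
  g <- igraph::graph_from_adjacency_matrix(R, mode = "undirected")
  expect_equal(networkModularity(R, labR, directed = FALSE),
               igraph::modularity(g, labR), tolerance = 1e-12)
})

test_that("partition edit distance matches a DP Levenshtein oracle", {
  net <- generateGroundTruthNetwork(100, seed = 103)
  pl <- plantedPartition(net)
  expect_identical(partitionEditDistance(net, net, pl, pl), 0L)
  # one flipped intra-module entry costs exactly 1
  A <- adjacency(net)
  lab <- moduleLabels(net)
  idx <- which(outer(lab, lab, "==") & A == 1L & row(A) != col(A))[1]
  B <- A; B[idx] <- 0L
  expect_identical(partitionEditDistance(A, B, pl, pl), 1L)
  # 3-vertex module toy against the standard DP on the 9-character strings
  a3 <- matrix(c(0, 1, 0, 0, 0, 1, 1, 0, 0), 3, 3, byrow = TRUE)
  b3 <- matrix(c(0, 0, 1, 1, 0, 0, 0, 1, 0), 3, 3, byrow = TRUE)
  one <- Partition(rep(1, 3))
  sA <- paste(as.vector(t(a3)), collapse = "")
  sB <- paste(as.vector(t(b3)), collapse = "")
  expect_identical(partitionEditDistance(a3, b3, one, one),
                   as.integer(dp_levenshtein(sA, sB)))
})

test_that("partition metrics ignore label names entirely", {
  d <- benchmark_draw()
  p <- detectModules(d$net, "louvain_directed", seed = 5)
  lab <- moduleLabels(p)
  shuffled <- Partition(max(lab) + 1L - lab) # reversed ids
  expect_equal(coverage(d$net, p), coverage(d$net, shuffled))
  expect_equal(partitionPerformance(d$net, p), partitionPerformance(d$net, shuffled))
  expect_equal(networkModularity(d$net, p), networkModularity(d$net, shuffled))
  pl <- plantedPartition(d$net)
  expect_equal(randIndex(pl, p), randIndex(pl, shuffled))
  expect_equal(correctClassifiedRatio(pl, p), correctClassifiedRatio(pl, shuffled))
})
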