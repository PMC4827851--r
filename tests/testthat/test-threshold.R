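# Percentile and kappa-optimal dichotomization, connectedness, ROC.

test_that("percentile thresholds match an order-statistic oracle", {
  g <- matrix(NA_real_, 11, 11)
  g[row(g) != col(g)] <- sample(1:110)
  # constant weights: the threshold equals that value for any q
  gc <- matrix(5, 4, 4)
  expect_equal(percentileThreshold(gc, 90), 5)
  expect_equal(percentileThreshold(gc, 10), 5)
  # linear-interpolation oracle computed from sorted order statistics
  w <- sort(g[row(g) != col(g)])
  for (q in c(90, 95, 98)) {
    h <- 1 + (length(w) - 1) * q / 100
    oracle <- w[floor(h)] + (h - floor(h)) * (w[ceiling(h)] - w[floor(h)])
    expect_equal(percentileThreshold(g, q), oracle)
  }
  expect_error(percentileThreshold(g, 0))
  expect_error(percentileThreshold(g, 100))
})

test_that("binarize keeps strictly supra-threshold edges with zero diagonal", {
  g <- matrix(c(0, 5, 1, 2,
                9, 0, 3, 8,
                1, 7, 0, 2,
                6, 1, 2, 0), 4, 4, byrow = TRUE)
  diag(g) <- NA
  B <- binarize(g, 4) # exactly 5 entries exceed 4
  expect_identical(sum(B), 5L)
  expect_true(all(diag(B) == 0))
  expect_identical(B[1, 2], 1L) # g[1,2] = 5 > 4
  expect_identical(B[1, 3], 0L)
  # below the minimum: complete digraph minus diagonal; above max: empty
  expect_identical(sum(binarize(g, 0)), 12L)
  expect_identical(sum(binarize(g, 9)), 0L)
  expect_identical(sum(binarize(g, min(g, na.rm = TRUE))), 9L) # three ties at 1 dropped
})

test_that("the kappa sweep finds the analytic optimum", {
  # construct off-diagonal agreement counts (44, 11, 11, 44) at the optimal
  # cutoff: kappa = (0.8 - 0.5) / (1 - 0.5) = 0.6
  D <- 11
  off <- which(row(diag(D)) != col(diag(D)))
  truth <- matrix(0L, D, D)
  set.seed(71)
  pos <- sample(off, 55)
  truth[pos] <- 1L
  w <- matrix(0, D, D)
  w[pos] <- 2 # true positives get high weight ...
  flipPos <- sample(pos, 11); w[flipPos] <- 0          # ... except 11 misses
  flipNeg <- sample(setdiff(off, pos), 11); w[flipNeg] <- 2 # 11 false alarms
  thr <- kappaOptimalThreshold(w, truth)
  expect_equal(attr(thr, "kappa"), 0.6, tolerance = 1e-12)
  expect_true(thr >= 0 && thr < 2)
  # kappa at the returned threshold >= kappa at every candidate (exhaustive)
  for (cand in unique(w[off])) {
    B <- binarize(w, cand)
    tp <- sum(B[off] == 1 & truth[off] == 1); fp <- sum(B[off] == 1 & truth[off] == 0)
    fn <- sum(B[off] == 0 & truth[off] == 1); tn <- sum(B[off] == 0 & truth[off] == 0)
    n <- length(off)
    po <- (tp + tn) / n
    pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
    expect_lte((po - pe) / (1 - pe), attr(thr, "kappa") + 1e-12)
  }
})

test_that("kappa threshold separates a noisy copy of the truth perfectly", {
  net <- generateGroundTruthNetwork(100, seed = 72)
  A <- adjacency(net)
  set.seed(72)
  g <- A + matrix(runif(100 * 100, 0, 0.4), 100, 100)
  diag(g) <- NA
  thr <- kappaOptimalThreshold(g, net)
  expect_equal(as.numeric(attr(thr, "kappa")), 1)
  expect_identical(unname(binarize(g, thr) + 0L), unname(A + 0L))
  # truth-independent weights give chance-level kappa
  gp <- matrix(runif(100 * 100), 100, 100); diag(gp) <- NA
  expect_lt(attr(kappaOptimalThreshold(gp, net), "kappa"), 0.1)
  # degenerate truth is refused
  expect_error(kappaOptimalThreshold(gp, matrix(0L, 100, 100)), "degenerate")
})

test_that("connectedness agrees with a breadth-first-search oracle", {
  cyc <- matrix(0L, 5, 5)
  cyc[cbind(c(2:5, 1), 1:5)] <- 1L # directed cycle
  expect_true(checkConnectedness(cyc))
  two <- matrix(0L, 6, 6)
  two[cbind(c(2, 3, 1), c(1, 2, 3))] <- 1L
  two[cbind(c(5, 6, 4), c(4, 5, 6))] <- 1L # two disjoint cycles
  expect_false(checkConnectedness(two))
  d <- benchmark_draw()
  g <- lsGci(d$y, p = 1, varTarget = 0.8)
  B <- binarize(g, percentileThreshold(g, 98))
  expect_identical(checkConnectedness(B), bfs_connected(B))
})

test_that("ROC analysis reproduces trivial cases and the U-statistic identity", {
  net <- generateGroundTruthNetwork(100, seed = 74)
  A <- adjacency(net)
  expect_equal(rocCurve(A + 0.0, net)$auc, 1) # weights equal to the truth
  # truth-independent weights give chance AUC
  set.seed(74)
  aucs <- vapply(1:5, function(s) {
    gp <- matrix(rnorm(1e4), 100, 100); diag(gp) <- NA
    rocCurve(gp, net)$auc
  }, numeric(1))
  expect_equal(mean(aucs), 0.5, tolerance = 0.05)
  # D = 6: AUC equals exhaustive pair counting (with ties)
  set.seed(75)
  truth6 <- matrix(rbinom(36, 1, 0.4), 6, 6); diag(truth6) <- 0L
  w6 <- matrix(sample(1:10, 36, replace = TRUE), 6, 6)
  off <- row(w6) != col(w6)
  r <- rocCurve(w6, truth6)
  expect_equal(r$auc, pairwise_auc(w6[off], truth6[off]), tolerance = 1e-12)
  expect_true(all(diff(r$tpr) >= 0) && all(diff(r$fpr) >= 0))
})

test_that("AUC is invariant under strictly monotone weight transforms", {
  d <- benchmark_draw()
  g <- gciValues(lsGci(d$y, p = 1, varTarget = 0.7))
  a1 <- rocCurve(g, d$net)$auc
  a2 <- rocCurve(exp(2 * g), d$net)$auc
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("ROC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(76)
  truth <- matrix(rbinom(400, 1, 0.1), 20, 20); diag(truth) <- 0L
  if (sum(truth[row(truth) != col(truth)]) == 0) truth[1, 2] <- 1L
  w <- matrix(rnorm(400), 20, 20)
  w[truth == 1] <- w[truth == 1] + 1
  diag(w) <- NA
  off <- row(w) != col(w)
  ours <- rocCurve(w, truth)$auc
  ref <- suppressMessages(as.numeric(pROC::auc(truth[off], w[off])))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("percentile binarization yields the expected edge densities", {
  d <- benchmark_draw()
  g <- lsGci(d$y, p = 1, varTarget = 0.8)
  nOff <- 100 * 99
  for (q in c(90, 95, 98)) {
    B <- binarize(g, percentileThreshold(g, q))
    expect_equal(sum(B) / nOff, (100 - q) / 100, tolerance = 0.005)
  }
})
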