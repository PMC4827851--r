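# Ground-truth network generator, AR parameterization, MVAR simulator.

test_that("generated networks satisfy every structural constraint", {
  for (s in 1:5) {
    net <- generateGroundTruthNetwork(100, seed = s)
    expect_true(validObject(net)) # validity enforces all invariants
    A <- adjacency(net)
    lab <- moduleLabels(net)
    expect_identical(length(moduleSizes(net)), 8L)
    expect_true(all(moduleSizes(net) >= 10 & moduleSizes(net) <= 15))
    expect_identical(sum(moduleSizes(net)), 100L)
    expect_true(all(diag(A) == 0))
    expect_true(all(colSums(A) <= 15))
    same <- outer(lab, lab, "==")
    expect_true(all(rowSums(A * same) >= 4))
    expect_true(all(colSums(A * same) >= 4))
    expect_true(all(rowSums(A * !same) <= 4))
    expect_true(all(colSums(A * !same) <= 4))
  }
  # module count scales with D: eight additional modules per 100 vertices
  expect_identical(length(moduleSizes(generateGroundTruthNetwork(200, seed = 1))), 16L)
})

test_that("generation is deterministic under a fixed seed", {
  a <- generateGroundTruthNetwork(100, seed = 42)
  b <- generateGroundTruthNetwork(100, seed = 42)
  expect_identical(adjacency(a), adjacency(b))
  expect_identical(moduleLabels(a), moduleLabels(b))
  c1 <- assignArCoefficients(a, seed = 9)
  c2 <- assignArCoefficients(b, seed = 9)
  expect_identical(coefMatrices(c1), coefMatrices(c2))
  y1 <- simulateMvar(c1, N = 50, seed = 3)
  y2 <- simulateMvar(c2, N = 50, seed = 3)
  expect_identical(y1, y2)
})

test_that("empirical edge densities match the generative probabilities", {
  # pooled over networks; the repair steps preserve the sampled edge counts,
  # so a binomial CI around p_int = 0.5 and p_ext = 3/85 applies (99.9%)
  nIntra <- 0; kIntra <- 0; nInter <- 0; kInter <- 0
  for (s in 1:12) {
    net <- generateGroundTruthNetwork(100, seed = 200 + s)
    A <- adjacency(net)
    lab <- moduleLabels(net)
    same <- outer(lab, lab, "==")
    diag(same) <- NA
    kIntra <- kIntra + sum(A[which(same)])
    nIntra <- nIntra + sum(same, na.rm = TRUE)
    kInter <- kInter + sum(A[which(!same)])
    nInter <- nInter + sum(!same, na.rm = TRUE)
  }
  z <- qnorm(0.9995)
  pIntra <- kIntra / nIntra
  expect_lt(abs(pIntra - 0.5), z * sqrt(0.5 * 0.5 / nIntra))
  pExt <- 3 / 85
  pInter <- kInter / nInter
  expect_lt(abs(pInter - pExt), z * sqrt(pExt * (1 - pExt) / nInter))
})

test_that("p_ext follows the 3/(D-15) rule", {
  net <- generateGroundTruthNetwork(100, seed = 1)
  expect_equal(net@params$pExt, 3 / 85)
  expect_equal(net@params$pExt, 0.0353, tolerance = 1e-2)
})

test_that("AR coefficients have support equal to the adjacency and scale 0.99/eta", {
  net <- generateGroundTruthNetwork(100, seed = 6)
  co <- assignArCoefficients(net, seed = 6)
  A1 <- coefMatrices(co)[[1]]
  A <- adjacency(net)
  expect_identical((A1 != 0) + 0L, A + 0L) # support equality
  eta <- max(colSums(A))
  expect_identical(co@eta, as.integer(eta))
  expect_true(eta <= 15)
  nz <- abs(A1[A1 != 0])
  expect_equal(max(abs(nz - 0.99 / eta)), 0, tolerance = 1e-12)
  # edgeless network gives a zero coefficient matrix
  edgeless <- matrix(0L, 5, 5)
  co0 <- assignArCoefficients(edgeless, seed = 1)
  expect_true(all(coefMatrices(co0)[[1]] == 0))
})

test_that("stationarity check equals the dense companion eigenvalue oracle", {
  expect_equal(checkStationarity(list(matrix(0, 4, 4))), 0)
  expect_equal(checkStationarity(list(diag(0.5, 4))), 0.5)
  # random benchmark draw vs direct eigen computation on the companion matrix
  net <- generateGroundTruthNetwork(100, seed = 13)
  co <- assignArCoefficients(net, seed = 13)
  A1 <- coefMatrices(co)[[1]]
  oracle <- max(Mod(eigen(A1, only.values = TRUE)$values))
  expect_equal(checkStationarity(co), oracle, tolerance = 1e-12)
  expect_lt(oracle, 1) # accepted draws are stationary
  # order-2 companion: radius of [[a1, a2], [I, 0]]
  a <- list(diag(0.4, 3), diag(0.2, 3))
  comp <- rbind(cbind(a[[1]], a[[2]]), cbind(diag(3), matrix(0, 3, 3)))
  expect_equal(checkStationarity(a),
               max(Mod(eigen(comp, only.values = TRUE)$values)),
               tolerance = 1e-12)
})

test_that("simulated series have the requested shape and dynamics", {
  d <- benchmark_draw()
  expect_identical(dim(d$y), c(100L, 1000L)) # N held constant at 1000
  expect_true(all(is.finite(d$y)))
  # zero coefficients: the output is exactly the innovation draw
  co0 <- new("ArCoefficients", A = list(matrix(0, 3, 3)), eta = 0L, order = 1L)
  y0a <- simulateMvar(co0, N = 100, burnIn = 0, seed = 5)
  y0b <- simulateMvar(co0, N = 100, burnIn = 0, seed = 5)
  expect_identical(y0a, y0b)
  eps <- local({
    set.seed(lsgc:::.deriveSeed(5, "innovations"))
    matrix(rnorm(300), 3, 100)
  })
  expect_equal(y0a, eps) # no dynamics: output is the innovation draw itself
  expect_equal(sd(as.vector(y0a)), 1, tolerance = 0.2)
  # univariate AR(1) with a = 0.9: lag-1 autocorrelation ~= 0.9 at N = 1e5
  co9 <- new("ArCoefficients", A = list(matrix(0.9, 1, 1)), eta = 1L, order = 1L)
  y9 <- simulateMvar(co9, N = 1e5, seed = 8)
  r1 <- cor(y9[1, -1], y9[1, -ncol(y9)])
  expect_equal(r1, 0.9, tolerance = 0.01)
  # non-stationary coefficients are refused with the radius in the message
  bad <- new("ArCoefficients", A = list(matrix(1.1, 1, 1)), eta = 1L, order = 1L)
  expect_error(simulateMvar(bad, N = 10, seed = 1), "radius")
})

test_that("invalid module structures are rejected, not repaired silently", {
  net <- generateGroundTruthNetwork(100, seed = 2)
  A <- adjacency(net)
  A[, 1] <- 0L # strip vertex 1 of in-edges on the column axis
  expect_error(new("ModularNetwork", adjacency = A,
                   labels = moduleLabels(net),
                   moduleSizes = moduleSizes(net), params = list()),
               "intra-module")
})
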