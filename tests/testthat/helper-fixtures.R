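# Shared fixtures, computed once per test run and cached in an environment.
# The desk-scale benchmark fixture (8 realizations at D = 100, N = 1000)
# backs the edge-recovery and module-recoverability checks; the reference
# study uses 100 realizations, and scripts/acceptance.R uses 20.

.fixtureCache <- new.env(parent = emptyenv())

benchmark_fixture <- function() {
  if (!is.null(.fixtureCache$benchmark)) return(.fixtureCache$benchmark)
  cfg <- studyConfig(dims = 100L, nSamples = 1000L, realizations = 8L,
                     varTargets = c(0.7, 0.8, 0.9, 1.0), p = 1L,
                     masterSeed = 20160411L)
  .fixtureCache$benchmark <- runBenchmark(cfg)
  .fixtureCache$benchmark
}

# One benchmark draw (network, coefficients, series), shared by cheap tests.
benchmark_draw <- function() {
  if (!is.null(.fixtureCache$draw)) return(.fixtureCache$draw)
  net <- generateGroundTruthNetwork(100, seed = 11)
  coeffs <- assignArCoefficients(net, seed = 11)
  y <- simulateMvar(coeffs, N = 1000, seed = 11)
  .fixtureCache$draw <- list(net = net, coeffs = coeffs, y = y)
  .fixtureCache$draw
}
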