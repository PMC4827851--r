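# End-to-end benchmark orchestration: simulate ground truth, estimate
# (ls)GCI, dichotomize, detect modules, score. Every output row carries
# (seed, D, varTarget, algorithm) provenance; the whole study is
# reconstructible from the config plus the master seed.

.defaultAlgorithms <- c("leading_eigenvector_directed", "louvain_directed",
                        "walktrap", "fast_greedy", "leading_eigenvector",
                        "spinglass", "louvain")

#' Benchmark study configuration
#'
#' Validates and freezes the settings of a simulation study. The default
#' configuration is the full benchmark (N = 1000 samples, order
#' p = 1, variance targets 70-100%, 100 realizations); \code{scale}
#' proportionally reduces the number of realizations for desk-scale runs.
#'
#' @param dims network dimensions to simulate (multiples of 100 are the
#'   benchmark grid).
#' @param nSamples temporal samples N per realization.
#' @param realizations realizations per dimension (before scaling).
#' @param varTargets variance-explanation settings; 1.0 denotes the classical
#'   GCI.
#' @param p MVAR model order.
#' @param percentiles percentile operating points for reporting.
#' @param algorithms module-detection algorithms (see [detectModules()]).
#' @param masterSeed master seed; per-realization seeds are derived
#'   deterministically, so any subset of the study can be recomputed
#'   independently.
#' @param scale multiplier in (0, 1] applied to \code{realizations}.
#' @return A validated config (class \code{StudyConfig}).
#' @export
studyConfig <- function(dims = 100L, nSamples = 1000L, realizations = 100L,
                        varTargets = c(0.7, 0.8, 0.9, 1.0), p = 1L,
                        percentiles = c(90, 95, 98),
                        algorithms = .defaultAlgorithms,
                        masterSeed = 1L, scale = 1) {
  stopifnot(scale > 0, scale <= 1, all(varTargets > 0), all(varTargets <= 1))
  algorithms <- match.arg(algorithms, c(.defaultAlgorithms, "infomap"),
                          several.ok = TRUE)
  for (D in dims) {
    # C can reach D at varTarget = 1, so validate the worst case up front
    if (!feasibleOrder(as.integer(D), nSamples, p))
      stop(sprintf("infeasible config: D = %d needs N - p >= C * p up to C = D (N = %d, p = %d)",
                   D, nSamples, p))
  }
  cfg <- list(dims = as.integer(dims), nSamples = as.integer(nSamples),
              realizations = max(1L, as.integer(round(realizations * scale))),
              varTargets = varTargets, p = as.integer(p),
              percentiles = percentiles, algorithms = algorithms,
              masterSeed = as.integer(masterSeed))
  class(cfg) <- "StudyConfig"
  cfg
}

# One benchmark realization: returns list(roc = df, modules = df).
.benchmarkRealization <- function(D, realization, cfg) {
  seed <- .deriveSeed(cfg$masterSeed, sprintf("realization-%d", D), realization)
  net <- generateGroundTruthNetwork(D, seed = seed)
  coeffs <- assignArCoefficients(net, seed = seed)
  y <- simulateMvar(coeffs, N = cfg$nSamples, seed = seed)
  planted <- plantedPartition(net)

  rocRows <- list(); modRows <- list()
  # partitions detected on the ground-truth network
  truthParts <- list()
  for (alg in cfg$algorithms) {
    pt <- detectModules(net, alg, seed = seed)
    truthParts[[alg]] <- pt
    modRows[[length(modRows) + 1L]] <- data.frame(
      seed = seed, D = D, network = "truth", varTarget = NA_real_,
      algorithm = alg, kDetected = nModules(pt),
      threshold = NA_real_, kappa = NA_real_,
      correctRatio = correctClassifiedRatio(planted, pt),
      randPlanted = randIndex(planted, pt),
      randVsTruthPartition = NA_real_, ari = NA_real_, mi = NA_real_,
      vi = NA_real_, splitJoin = NA_integer_, editDistance = NA_integer_,
      coverage = coverage(net, pt),
      performance = partitionPerformance(net, pt),
      modularity = networkModularity(net, pt, directed = TRUE))
  }

  for (v in cfg$varTargets) {
    cm <- lsGci(y, p = cfg$p, varTarget = v)
    roc <- rocCurve(cm, net)
    rocRows[[length(rocRows) + 1L]] <- data.frame(
      seed = seed, D = D, varTarget = v, C = cm@nComponents,
      estimator = cm@estimator, auc = roc$auc)
    thr <- kappaOptimalThreshold(cm, net)
    B <- binarize(cm, thr)
    for (alg in cfg$algorithms) {
      pl <- try(detectModules(B, alg, seed = seed), silent = TRUE)
      if (inherits(pl, "try-error")) {
        modRows[[length(modRows) + 1L]] <- data.frame(
          seed = seed, D = D, network = "lsgc", varTarget = v,
          algorithm = alg, kDetected = NA_integer_,
          threshold = as.numeric(thr), kappa = attr(thr, "kappa"),
          correctRatio = NA_real_, randPlanted = NA_real_,
          randVsTruthPartition = NA_real_, ari = NA_real_, mi = NA_real_,
          vi = NA_real_, splitJoin = NA_integer_, editDistance = NA_integer_,
          coverage = NA_real_, performance = NA_real_, modularity = NA_real_)
        next
      }
      pt <- truthParts[[alg]]
      mm <- matchModules(pt, pl)
      modRows[[length(modRows) + 1L]] <- data.frame(
        seed = seed, D = D, network = "lsgc", varTarget = v,
        algorithm = alg, kDetected = nModules(pl),
        threshold = as.numeric(thr), kappa = attr(thr, "kappa"),
        correctRatio = correctClassifiedRatio(planted, pl),
        randPlanted = randIndex(planted, pl),
        randVsTruthPartition = randIndex(pt, pl),
        ari = adjustedRand(pt, pl),
        mi = mutualInformation(pt, pl),
        vi = variationOfInformation(pt, pl),
        splitJoin = splitJoinDistance(pt, pl),
        editDistance = partitionEditDistance(net, B, pt, pl, matching = mm),
        coverage = coverage(B, pl),
        performance = partitionPerformance(B, pl),
        modularity = networkModularity(B, pl, directed = TRUE))
    }
  }
  list(roc = do.call(rbind, rocRows), modules = do.call(rbind, modRows))
}

#' Run the edge-recovery and module-recoverability benchmark
#'
#' For every configured dimension and realization: generates a ground-truth
#' network and its MVAR time series, computes the lsGCI connectivity at every
#' variance target (classical GCI at 1.0), scores ROC edge recovery against
#' the planted adjacency, dichotomizes at the Cohen's-kappa-optimal
#' threshold, detects modules with every configured algorithm on both the
#' ground-truth and the dichotomized lsGCI networks, and computes the full
#' battery of partition quality and similarity measures. Failed realizations
#' are logged and excluded, with counts reported.
#'
#' @param config a [studyConfig()] object.
#' @param verbose print per-realization progress to stderr.
#' @return List with tidy data frames \code{roc} (one row per realization and
#'   variance target) and \code{modules} (one row per realization, network
#'   kind, variance target and algorithm), the \code{failures} log, and the
#'   \code{config}.
#' @export
runBenchmark <- function(config = studyConfig(), verbose = FALSE) {
  stopifnot(inherits(config, "StudyConfig"))
  roc <- list(); modules <- list(); failures <- list()
  for (D in config$dims) {
    for (r in seq_len(config$realizations)) {
      if (verbose)
        message(sprintf("benchmark D = %d, realization %d/%d",
                        D, r, config$realizations))
      out <- tryCatch(.benchmarkRealization(D, r, config),
                      error = function(e) e)
      if (inherits(out, "error")) {
        failures[[length(failures) + 1L]] <- data.frame(
          D = D, realization = r, message = conditionMessage(out))
      } else {
        roc[[length(roc) + 1L]] <- out$roc
        modules[[length(modules) + 1L]] <- out$modules
      }
    }
  }
  list(config = config,
       roc = if (length(roc)) do.call(rbind, roc) else NULL,
       modules = if (length(modules)) do.call(rbind, modules) else NULL,
       failures = if (length(failures)) do.call(rbind, failures) else
         data.frame(D = integer(), realization = integer(),
                    message = character()))
}

#' Estimate connectivity and modules for a time-series matrix file
#'
#' Real-data entry point mirroring the benchmark pipeline on a single matrix:
#' reads a delimited time-series matrix (rows = series), computes the lsGCI
#' connectivity, dichotomizes at a percentile threshold, reports
#' connectedness, detects modules, and writes all outputs as plain-text
#' files into \code{outDir}.
#'
#' @param input path of a TSV/whitespace-delimited matrix (rows = series), or
#'   a numeric matrix.
#' @param outDir output directory (created if missing).
#' @param p MVAR model order.
#' @param varTarget variance-explanation target in (0, 1].
#' @param percentile edge-weight percentile for dichotomization.
#' @param algorithm module-detection algorithm.
#' @param seed seed for stochastic detection.
#' @return Invisibly, a list with the connectivity matrix, binary network,
#'   partition, and a summary data frame (also written to
#'   \code{summary.tsv}).
#' @export
runConnectivity <- function(input, outDir, p = 1L, varTarget = 0.8,
                            percentile = 95, algorithm = "louvain_directed",
                            seed = 1L) {
  y <- if (is.matrix(input)) input else readTimeSeries(input)
  if (!is.numeric(y) || nrow(y) < 2L)
    stop("input must be a numeric matrix with at least 2 rows (series)")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cm <- lsGci(y, p = p, varTarget = varTarget)
  thr <- percentileThreshold(cm, percentile)
  B <- binarize(cm, thr)
  connected <- checkConnectedness(B)
  part <- detectModules(B, algorithm, seed = seed)
  writeConnectivity(cm, file.path(outDir, "lsgc.tsv"))
  writeEdgeList(B, file.path(outDir, "network.tsv"))
  writePartition(part, file.path(outDir, "partition.tsv"))
  summary <- data.frame(
    D = nrow(y), N = ncol(y), p = p, varTarget = varTarget,
    C = cm@nComponents, varExplained = cm@varExplained, estimator = cm@estimator,
    percentile = percentile, threshold = thr,
    edgeDensity = sum(B) / (nrow(B) * (nrow(B) - 1L)),
    connected = connected, algorithm = algorithm, seed = seed,
    kDetected = nModules(part), modularity = part@modularity,
    coverage = coverage(B, part),
    performance = partitionPerformance(B, part))
  write.table(summary, file.path(outDir, "summary.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(list(connectivity = cm, network = B, partition = part,
                 summary = summary))
}
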