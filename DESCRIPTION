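Package: lsgc
Title: Large-Scale Granger Causality for High-Dimensional Time Series Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Fully multivariate Granger causality for high-dimensional
    multivariate time series via a PCA-embedded dimension reduction with
    residual back-projection (large-scale Granger Causality index, lsGCI),
    together with the classical multivariate Granger Causality index,
    least-squares MVAR model fitting and order selection, a modular
    ground-truth network and MVAR time-series simulator for benchmarking,
    connectivity-matrix dichotomization (percentile and Cohen's-kappa-optimal
    thresholds), ROC-based edge-recovery evaluation, adapters for seven
    network community detection algorithms including directed variants, and a
    complete set of partition-quality and partition-similarity measures
    (correctly-classified ratio with Jaccard-cost assignment matching, Rand
    and adjusted Rand indices, mutual information, variation of information,
    split-join distance, coverage, performance, Newman-Girvan and
    Leicht-Newman modularity, and partition edit distance).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
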