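---
title: "Large-scale Granger causality: model, benchmark and design notes"
author: "lsgc package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Large-scale Granger causality: model, benchmark and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lsgc)
```

## The problem

Multivariate Granger causality asks, for every ordered pair of observed time
series, whether the past of one series improves the prediction of another
beyond what the remaining series already provide. The classical answer fits a
D-variate autoregressive (MVAR) model of order p,

$$Y(n) = \sum_{r=1}^{p} A_r\, Y(n-r) + E(n),$$

and compares the residual variance of each target equation between the full
model and a model refitted with the candidate source series removed:

$$\gamma_{i \to j} = \ln\!\big(\Sigma^{i-}_j / \Sigma_j\big).$$

The least-squares fit requires $N - p \ge K\,p$ for a K-variate model, so
truly high-dimensional recordings (thousands of series, hundreds of samples —
the typical shape of voxel-level fMRI data) cannot be fitted directly.

The large-scale Granger causality index (lsGCI) computed by `lsGci()` keeps
the vertex-by-vertex resolution while fitting only low-dimensional models:

1. project the row-centered data onto the leading C principal components,
   $x = W y$, with C chosen as the smallest count reaching a target variance
   fraction;
2. fit a C-variate MVAR model and back-project its predictions,
   $\hat e(n) = y(n) - W^{+}\hat x(n)$, where $W^{+}$ is the Moore–Penrose
   pseudoinverse ($W^\top$ for the orthonormal full-data mixing matrix);
3. for each candidate source i, delete row i of the data *and* column i of
   W, refit the C-variate model on $x^{i-} = W^{i-} y^{i-}$, and back-project
   through $(W^{i-})^{+}$;
4. form $\tilde\gamma_{i\to j}$ as the log ratio of the high-dimensional
   residual variance diagonals, exactly as in the classical index.

At 100% retained variance ($C = D$) the procedure reproduces the classical
GCI to machine precision — the package's primary correctness gate, asserted
in the test suite at $10^{-6}$ and against an independent straight-line
implementation at $10^{-8}$. At $C < D$ the back-projected models are no
longer nested least-squares fits, so finite-sample lsGCI values can be
(slightly) negative; the package never clips them.

Only the single-PCA column-deletion variant is implemented. The alternative
(a separate PCA per source cancellation) is deliberately out of scope: the
column-deletion variant needs only one decomposition for all D cancellations
and is the better performer of the two in simulation comparisons.

## Tunable parameters

* `p` — MVAR model order. The synthetic benchmark generates order-1
  processes and order selection by `selectOrderAic()` uses the multivariate
  AIC $(N-p)\ln\det\Sigma(p) + 2K^2p$; for resting-state fMRI-like data an
  order around 5 is typical.
* `varTarget` — retained cumulative eigenvalue fraction, in (0, 1]. Values
  around 0.8 are a practical sweet spot; below about 0.65 the reduction
  discards too much connectivity information, and 1.0 recovers the classical
  GCI (only feasible when $N - p \ge D\,p$).
* `N` — samples per series. The benchmark holds $N = 1000$; estimator
  quality improves with N and degrades slowly with D.

Numerical choices: fits use a pivoted QR decomposition (`lm.fit`), refusing
rank-deficient regressors in the user-facing `fitMvar()` with a
condition-number diagnostic, while the internal lsGCI path tolerates the
structural rank deficiency that arises at $C = D$ (fitted values — orthogonal
projections — remain unique). Covariances are computed over $n = p+1..N$
with the $1/(N-p)$ normalization and no re-centering (the models are
intercept-free fits to row-centered data; the GCI is a ratio of diagonals,
so the normalization cancels). PCA is computed on the smaller of the spatial
and temporal Gram matrices (identical spectra by duality); eigenvector signs
are fixed by making each component's largest-magnitude loading positive, a
pure reporting convention that the lsGCI is provably invariant to (flipping
a row of W flips $\hat x$ and the corresponding column of $W^{+}$, leaving
every residual unchanged).

## The synthetic benchmark

`generateGroundTruthNetwork()` plants a modular directed network: modules of
10–15 vertices (eight per 100 vertices), directed intra-module edges with
probability 0.5, inter-module edges with probability $3/(D-15)$ (so each
vertex averages three inter-module edges per direction), adjacency column
sums capped at 15, at least 4 intra-module and at most 4 inter-module edges
per vertex and direction. Constraint satisfaction uses bounded local repair
that *preserves the sampled edge counts*: additions for degree deficits are
compensated by removals of freely removable edges, and trimmed inter-module
excess edges are moved to feasible pairs. The empirical intra/inter densities
therefore match the nominal probabilities (verified by binomial-CI tests),
while every hard constraint holds exactly; generation fails loudly rather
than relaxing a constraint.

`assignArCoefficients()` sets $A^1_{ij} = \rho \cdot 0.99/\eta$ on the
adjacency support, with $\rho$ uniform on $\{-1, +1\}$ per edge and $\eta$
the maximum adjacency column sum. This scale bounds the maximum absolute row
sum of $A^1$ near 0.99, which guarantees stationarity by the induced-norm
bound; the package still verifies the companion spectral radius and redraws
the signs (deterministically, from an incremented sub-seed) in the
exceptional case of a radius at or above one. Innovations are i.i.d. standard
normal; `simulateMvar()` starts from a zero state and discards a 500-sample
burn-in (both are free modelling choices, so these are package
choices, documented here: the burn-in removes the transient many times over
at the benchmark's spectral radius of about 0.2).

One seed drives the whole generator through a deterministic hierarchical
sub-seed derivation (separate streams for network structure, coefficient
signs and innovations), so any component of a study can be reproduced in
isolation, and fixed seeds give bit-identical networks, coefficients and
series.

What the simulator does *not* emulate: hemodynamic filtering, measurement
noise correlated across vertices, non-linear coupling, non-stationarity, and
the spatial autocorrelation of real imaging data. Passing benchmarks
therefore demonstrate correctness of the estimator and pipeline on linear
stationary modular processes, not performance on any particular real
recording.

## Dichotomization and evaluation

Connectivity matrices are dichotomized by `binarize()` with strict-inequality
retention (a q-th percentile threshold from `percentileThreshold()`, computed
over off-diagonal cells with the linear-interpolation convention, removes
about q% of candidate edges; ties at the threshold are dropped). For
benchmark evaluation, `kappaOptimalThreshold()` sweeps every unique
off-diagonal weight and maximizes Cohen's kappa against the ground-truth
adjacency, breaking ties toward the lowest cutoff (the densest of the equally
good networks). Connectedness (`checkConnectedness()`) is a filter and a
report — the pipeline never adjusts a threshold automatically. ROC analysis
(`rocCurve()`) uses edge presence as the status variable over off-diagonal
cells, with tied weights forming a single step and trapezoidal AUC (equal to
the Mann–Whitney U statistic).

## Module detection and partition scoring

`detectModules()` adapts seven algorithms behind one interface. Walktrap,
fast-greedy (Clauset–Newman–Moore), spinglass and Louvain run through their
igraph implementations; when an algorithm explores a hierarchy, the
maximal-modularity level is selected. Two design points deserve explanation:

* **Symmetrization for undirected algorithms.** Each directed edge is
  replaced by an undirected one, so a reciprocated pair contributes weight 2:
  the undirected algorithms receive $A + A^\top$. This multiplicity
  preservation matters. Intra-module pairs are reciprocated far more often
  (edge probability 0.5 per direction) than inter-module pairs, and the
  agglomerative detectors rely on exactly that contrast: with the weighted
  symmetrization the fast-greedy median correct-classification ratio on
  ground-truth networks is near 1.0, while collapsing to binary edges
  discards the reciprocity signal and caps fast-greedy around 0.7 — below
  the benchmark levels this pipeline reproduces. The standalone
  `symmetrizeNetwork()` helper still returns the plain binary collapse
  (undirected edge iff at least one arc), which is the convention used by
  `partitionPerformance()` and undirected modularity.
* **Leading-eigenvector variants.** The Leicht–Newman directed variant has
  no igraph implementation, and igraph's undirected `cluster_leading_eigen`
  omits the fine-tuning stage of the published algorithm, which makes it
  stall at coarse splits on these benchmarks. Both variants are therefore
  implemented in the package as recursive spectral bisection of the
  (symmetrized) directed modularity matrix with Kernighan–Lin fine-tuning
  after every split; the undirected variant is the same machinery applied to
  $A + A^\top$, to which the directed formulation reduces exactly.
  "Louvain directed" follows the same interpretation: greedy local moves and
  aggregation scoring the Leicht–Newman directed modularity.
* Infomap is wired in behind its flag but excluded from the default
  benchmark set (on dense real-data networks it tends to collapse to a
  single module).

Partition quality and similarity measures follow the standard definitions:
pair-counting Rand and Hubert–Arabie adjusted Rand; mutual information and
variation of information in nats; van Dongen split-join distance; coverage
(directed intra-module edge fraction); performance (fraction of correctly
"interpreted" unordered pairs, with "interacting" meaning at least one arc);
Newman–Girvan and Leicht–Newman modularity. The correctly-classified ratio
matches modules by minimising total Jaccard distance through an exact
$O(n^3)$ assignment solver (no approximation; surplus modules stay unmatched
and their vertices count as misclassified — the convention the measure's
known weakness under module splits makes explicit). The partition edit
distance vectorizes each matched module pair's intra-module adjacency —
aligned on the union of the two vertex sets, absent vertices padded as zero
rows and columns, row-major order — and sums Levenshtein distances.

## Benchmark scale

Per realization, `runBenchmark()` chains the full pipeline: ground-truth
network, MVAR series ($N = 1000$, $p = 1$), lsGCI at each variance target
(classical GCI at 1.0), ROC against the planted adjacency, kappa-optimal
dichotomization, module detection with all seven algorithms on both the
truth and the lsGCI networks, and the full measure battery; failed
realizations are logged and excluded with counts reported. The full
benchmark configuration uses 100 realizations per dimension; the test suite runs a
shared 8-realization fixture and `scripts/acceptance.R` runs 20 realizations
at $D = 100$, sizes chosen to keep a desk-scale run in minutes while leaving
medians stable; `studyConfig(scale = )` scales a configuration down
proportionally. Larger dimensions (several hundred) work unchanged but the
classical-GCI reference at those sizes is better suited to batch hardware.

## Known limitations

* Linear Granger causality only: non-linear coupling is invisible to the
  MVAR model by construction.
* No edge-level significance testing; dichotomization is deterministic
  (percentile or kappa-optimal), and kappa-optimal thresholds require a
  ground truth, so they exist only in simulation settings.
* The benchmark generator plants non-overlapping, non-hierarchical modules
  with binary edges and order-1 dynamics.
* `correctClassifiedRatio()` penalizes module splits harshly (by design);
  prefer the Rand index when detected and reference module counts differ.
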