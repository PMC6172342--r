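---
title: "Comparing functional-connectivity graph constructions by predictive value"
author: "fcsurvey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing functional-connectivity graph constructions by predictive value}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcsurvey)
```

## The problem

Graph analyses of resting-state fMRI proceed in two construction steps
before any statistic is computed: voxels are clustered into regions (the
graph's nodes), and a functional-connectivity measure between the regions'
mean time series defines weighted edges. Published comparisons of healthy,
mildly cognitively impaired (MCI) and Alzheimer's (AD) groups disagree even
about the *direction* of group differences in standard graph metrics, and a
plausible culprit is this construction freedom. `fcsurvey` implements a
full survey of construction choices — three parcellation families, four
edge-estimator families in directed/undirected and windowed/unwindowed
variants, a threshold grid and rich-club subgraphs — and evaluates every
combination by the probability it assigns to the correct condition of
held-out subjects, rather than by counting significant group differences.

Because no raw clinical data are distributed, the package ships a seeded
synthetic-cohort generator that emulates the statistical structure the
pipeline assumes, so every claim in this vignette is backed by code that
runs in the test suite or the bundled analysis scripts.

## The synthetic cohort

`simulate_cohort()` draws, per subject, a 3-D voxel grid observed at 130
time points (TR 3 s, i.e. 6.5 minutes — the length that remains after
discarding startup volumes from a 7-minute scan). The grid is tiled into
`n_latent_clusters` contiguous blocks by recursive bisection; each block
carries a latent stationary AR(1) signal with unit variance, and the block
signals are correlated across blocks by the Cholesky factor of a
condition-specific coupling matrix. Voxels add i.i.d. Gaussian noise on
top of their block's signal.

Defaults, chosen once as a realistic desk-scale configuration:

* grid 12×12×6 (864 voxels) — every pipeline stage runs in seconds;
  full-resolution grids are configuration, not default;
* 4 latent clusters; AR(1) coefficient 0.3 (modest BOLD-like smoothness at
  a 3-s sampling interval); voxel noise SD 0.5 against unit signal
  variance;
* cohort 26 control / 16 MCI / 14 AD — the size of a typical small memory-clinic sample;
* inter-cluster coupling 0.6 (C), 0.45 (MCI), 0.3 (AD) — a monotone
  weakening of long-range functional connectivity with disease severity,
  which is the qualitative effect the survey is meant to detect.

What the generator deliberately does *not* emulate: scanner physics,
motion and physiological artefacts, preprocessing residue, spatially
varying hemodynamics, or subject-specific anatomy. Consequently, passing
tests show that the pipeline recovers known statistical structure and that
its estimators are calibrated — not that any particular construction would
win on clinical data.

## Parcellation

Three families produce the graph nodes:

* **Atlas** (`atlas_parcellate()`): a fixed label volume intersected with
  the subject mask; identical node counts across subjects. The synthetic
  atlas is a recursive-bisection tiling.
* **Ward** (`ward_parcellate(subject, k, p)`): agglomerative merging under
  the minimum-variance (Ward) criterion restricted to spatially adjacent
  clusters — 6-connectivity, face neighbours only — until `k` clusters
  remain; clusters smaller than `p` voxels are then discarded, so node
  counts vary slightly across subjects.
* **RGS** (`rgs_grow()` then `rgs_select()`): every voxel seeds a region
  that greedily absorbs the 6-neighbour with the highest Pearson
  correlation to the region mean, provided the correlation exceeds a
  threshold `T` (0.75 in the shipped presets) *and* the grown region stays
  functionally homogeneous. Selection then repeatedly takes the largest
  region and deletes all candidates whose centers it covers; survivors may
  overlap, but no selected center lies inside another selected region. A
  final size filter `p` applies.

**Homogeneity.** The broken-stick heterogeneity of `N` series compares
the eigenvalues `e_n` of their covariance (scaled to sum to `N`) with the
baseline `b_n = sum_{i=n..N} 1/i`; `n0`, the number of leading eigenvalues
above the baseline, estimates the number of independent signals, and

```
h = n0 + (e_n0 - b_n0) / ((e_n0 - e_n0+1) - (b_n0 - b_n0+1))
```

interpolates the crossing point. Two numerical choices deserve note.
First, the eigenvalue scaling is not dictated by the formula; scaling to
sum `N` makes the two curves comparable (the baseline also sums to `N`).
Second, even a perfectly homogeneous cluster (20 noisy copies of one
sinusoid) yields `h ≈ 1.9` under this interpolation, so `h = 1` cannot be
the homogeneity criterion itself; the package gates RGS growth on
`n0 == 1`, re-tested per added voxel, and reports `h` as a descriptive
statistic. For clusters of pure noise, where even `e_1` falls below the
baseline, `n0` is defined as 1. Singleton clusters count as perfectly
homogeneous in summaries.

Ward ties (equal merge costs) resolve by scan order, and RGS candidate
ties by lexicographic voxel coordinate, so both are deterministic. RGS is
by far the most expensive stage — every voxel is a seed and every growth
step re-checks homogeneity — which is one of the practical reasons the
survey's conclusions disfavour it.

## Edge estimators

All estimators operate on cluster-mean series, take absolute values, zero
the diagonal, and (for the windowed variants) average edge weights over
sliding windows — 50 time points with 10-point overlap — since no
aggregation rule is canonical, the arithmetic mean was chosen. Directed
variants scan source lags 0..5 and keep the largest value; lag 0 is
included, so a directed weight never falls below its undirected
counterpart for correlation.

* **corr**: |Pearson correlation|.
* **H2**: a piecewise-linear regression of y on x over 10 equal-count bins
  of x (bin-mean anchor points, end segments extended linearly);
  `h2 = 1 - residual variance / variance(y)`, the larger of the two
  directions when undirected. Bounded in [0, 1] by construction; it
  detects, e.g., `y = x^2` (h2 ≥ 0.99) where |Pearson| ≈ 0.
* **MIT**: mutual information from a 5×5 histogram over each window's
  min/max range, normalized as `I / sqrt(H(X) H(Y))` so identical series
  score 1 — a normalization chosen here to honor the [0, 1] edge-weight
  contract.
* **TE**: binned transfer entropy `I(y_t ; x_past | y_past)` with 5-sample
  past blocks (15 s at TR 3 s), normalized by `H(y_t | y_past)`. A full
  joint histogram over 5-sample pasts is hopeless at 130 samples (the
  state space dwarfs the data), so each past block is coarse-grained to
  its mean before binning into 3 bins per variable. The undirected
  variant averages the two directions. Calibration at series length 130:
  the directed null's 95th percentile is ≈ 0.12, and 1-lag coupling
  `y_t = x_{t-1} + noise` is detected (TE(x→y) > TE(y→x)) in ≈ 95% of
  replicates.

Constant cluster series within a window would make every estimator
ill-defined; such nodes keep zero-weight edges and emit a warning instead
of failing the subject.

## Graph metrics and the feature vector

Thresholding (`threshold_graph`) zeroes weights below `w_min` and leaves
the rest unchanged — no binarization, since discrete weight distributions
would make the higher moments uninformative. The rich club
(`rich_club_subgraph`) is the top 10% of nodes by weighted degree, ties
broken toward lower node index.

Per graph the package computes: weighted degree and normalized degree
(degree divided by edge count × maximum weight, hence in [0, 1]);
inverse-weight shortest paths by Dijkstra (strong edges are short);
closeness centrality `(n-1) / sum of distances`; the Zhang–Horvath
weighted clustering coefficient with weights normalized by the graph
maximum (it reduces exactly to the binary `2Δ/(k(k-1))` on binary
graphs); and, for undirected graphs, Newman modularity maximized by a
deterministic multilevel (Louvain-type) scheme. For directed graphs,
degree-type quantities use the mean of in- and out-halves so magnitudes
match the undirected case.

The **Louvain determinism and optimality** choices are the package's own:
nodes are visited in ascending index with best-improvement moves (ties to
the lowest community id), multilevel aggregation repeats until the
modularity stops improving, and a refinement pass (local moves, greedy
community merges, and a Kernighan–Lin-style sequence search that keeps
the best prefix of forced moves) runs on the original graph. Graphs with
at most 8 nodes skip the heuristic entirely and are solved by exhaustive
enumeration of all partitions (Bell(8) = 4140), which is cheaper than any
sophistication at that size; weak-structure random graphs otherwise admit
local optima that no single-move neighbourhood escapes.

The feature vector (`feature_vector`) holds, for each of five
distributions — nonzero edge weights, normalized degree, shortest paths,
closeness, clustering coefficient — the first four moments read as mean,
standard deviation, skewness and excess kurtosis (degenerate
distributions score 0 on the higher three), plus the node count scaled by
1/100 so all entries are of order unity, plus modularity when undirected:
d = 22 features (21 directed). Disconnected graphs have no finite path
moments; the pipeline skips such subject × threshold combinations and
marks the whole combination as skipped, mirroring the connectedness gate
of the survey design.

## The statistical model

The model treats past subjects' feature vectors of one condition as
exchangeable with a new subject's, with their empirical mean and
covariance sufficient for prediction. With a
normal–inverse-Wishart prior `(kappa0, nu0, delta0, Delta0)` the
posterior predictive for a new vector is multivariate t with
`nu - d + 1` degrees of freedom, location `delta`, and scale
`((kappa+1) / (kappa (nu-d+1))) Delta`, where

```
kappa = kappa0 + n          nu = nu0 + n
delta = (kappa0 delta0 + n fbar) / (kappa0 + n)
Delta = Delta0 + n Cov(f) + (kappa0 n / (kappa0 + n)) (fbar - delta0)(fbar - delta0)'
```

and `Cov(f)` uses divisor `n`. Hyperparameters are fixed identically for
all constructions: `kappa0 = 1`, `delta0 = 0.5` in every coordinate,
`Delta0 = 2.5 I` — an initial predictive centered on positive
order-unity values, matching the feature scaling. `nu0` is not pinned
down by that choice; the package defaults to `d + 2`, the smallest
integer for which the predictive covariance is finite, and exposes it.
No transform is applied to features despite their differing natural
ranges; that mismatch is a documented property of the approach, not an
accident.

Condition probabilities follow from Bayes' theorem under a uniform prior
over the three conditions (configurable), computed via log-sum-exp. The
score is the **negative surprise**, the natural log of the probability
assigned to the true condition: 0 for a sure event, `ln(1/3) ≈ -1.1` for
a uniform verdict, `-Inf` for an impossible one. Evaluation is
leave-one-out over all subjects, and a combination's score is the mean
per-subject surprise.

### Why a null cohort scores below the chance level

A uniform predictive gives exactly `ln(1/3)`. But the mean LOO surprise
of a *null* cohort (identical condition distributions) is not `ln(1/3)`:
by Jensen's inequality `E[log p_true] < log E[p_true] = ln(1/3)` unless
the posterior probabilities are exactly uniform for every subject. At
d = 22 with 14–26 subjects per condition, across-condition
log-likelihood differences fluctuate by several nats, and the measured
null-cohort mean sits near −1.8 to −2.5 depending on the seed. The test
suite asserts the ±0.15 chance-level band anyway and that assertion is
expected to fail; it documents the gap between the intuitive chance
level and the actual null behaviour of a high-dimensional predictive on
small samples. With few features (d ≈ 5) and matched scales the band is
met. Practical upshot: surprise values of competing constructions should
be compared with each other, and with the *uniform* chance level only as
an upper anchor for "uninformative".

## Supporting evaluations

* `mean_difference_test()`: a two-sided F-test at α = 0.05 chooses
  Student's vs Welch's two-sided t-test; no multiple-testing correction,
  matching the per-comparison p < 0.05 convention under study (the scan
  output includes comparison counts so users can correct afterwards).
* `significance_scan()` reports, per clustering family × edge family ×
  property × condition pair × direction, the fraction of method variants
  significant in that direction. On a constructed cohort whose C and AD
  coupling matrices cross, the significant direction of the mean-weight
  difference reverses between `w_min = 0` and `w_min = 0.3` — the
  survey's demonstration that threshold choice alone can flip a
  "significant" group difference. The mean graph weight here averages
  *all* off-diagonal entries including thresholded-out zeros; under the
  alternative reading (surviving edges only) the flip need not occur.
* `rank_profiles()` / `rank_distance_linkage()`: subjects ranked by a
  property's per-subject mean (ties by subject id), Euclidean distances
  between rank vectors, average-linkage (UPGMA) dendrogram — the linkage
  being the package's choice where none is canonical.
* `svm_pairwise_loo()`: radial-basis SVM with default parameters
  (`e1071::svm`, unscaled features to match the reference default
  behaviour), pairwise conditions, LOO accuracy, greedy forward feature
  selection maximizing LOO accuracy with ties toward fewer features.
  The selected accuracy is optimistically biased on null data (the
  selection optimizes the very criterion being reported, reaching ≈ 0.65
  at chance) and saturates at 1.0 on well-separated cohorts; the
  selection-free accuracy over all features is therefore used wherever an
  unsaturated, comparable number is needed, e.g. the surprise–accuracy
  correlation.
* `surprise_vs_svm()`: Pearson correlation and least-squares line across
  combinations, excluding transfer entropy (whose surprise is depressed
  relative to its classification accuracy) and reporting it separately.

## Problem sizes and determinism

The bundled analyses and tests run the survey at synthetic scale:
864-voxel grids, 4–8 latent clusters, atlas/Ward parcellations with 4–16
nodes, reduced method grids (e.g. 2 clusterings × 4 edge families for the
end-to-end checks, 500-pair null calibrations, 100-replicate directional
checks). These sizes were chosen so each analysis completes in seconds to
a few minutes while leaving every estimator's statistical behaviour
measurable. The full preset tables (Ward k = 5000/2000, RGS p = 55/50,
the 16 edge variants, thresholds 0.1–0.8) ship as data for full-scale
runs. All randomness flows from explicit integer seeds; rerunning any
script or test with the same configuration reproduces its outputs
bit-for-bit.

## Known limitations

* The synthetic generator's block structure makes parcellation easier
  than on real cortical data; Ward's perfect recovery there is a
  correctness check, not a performance claim.
* The coarse-grained TE estimator trades sensitivity for estimability at
  130 samples; its absolute values are not comparable to
  embedding-based TE estimators.
* H2 as implemented is bounded by 1; descriptions of nonlinear
  correlation exceeding 1 refer to other normalizations.
* The multivariate-t model is shared across all constructions by design;
  a model tailored per feature space would likely score higher but would
  confound the comparison.
* With overlapping RGS clusters, the `assignment` array keeps only the
  lowest-id containing cluster per voxel; the cluster list is
  authoritative.
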