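---
title: "Dynamic functional connectivity states: models and methods"
author: "dfcstates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic functional connectivity states: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfcstates)
```

## The problem

Resting-state fMRI connectivity is usually summarized by a single
correlation per network pair over a whole scan, which hides the fact that
between-network coupling reorganizes on the scale of tens of seconds. This
package implements a sliding-window analysis of that temporal structure for
per-subject network time courses (a T x N matrix per subject, e.g. 128 time
points at TR = 3 s for N = 27 resting-state networks): window-wise
regularized connectivity, recurring connectivity *states* found by
clustering, state dynamics metrics (frequency, dwell time, transitions),
time-resolved graph efficiency, and non-parametric group inference. It was
designed for three-group dementia cohorts (controls, Alzheimer's disease,
dementia with Lewy bodies), where the clinically interesting effects are a
reduced occupancy of a strongly connected state in patients, an increased
occupancy of a sparse state, and reduced temporal variability of global
network efficiency.

The raw MRI processing (ICA, dual regression, registration) is out of
scope: the pipeline starts from extracted network time courses in plain
TSV files.

## Pipeline and models

### Postprocessing

Each network time course is cleaned in three steps, in this order:

1. **Detrend** — least-squares removal of polynomial trends up to order 3
   (plus intercept), via projection on an orthogonal polynomial basis. The
   residual is exactly orthogonal to the basis and the operation is
   idempotent.
2. **Despike** — deviations from a running median (window 11 samples) are
   compared to a robust local scale (running MAD, scaled by 1.4826).
   Points beyond `madThreshold` (default 4) robust SDs are replaced by a
   cubic spline fitted through the clean samples. Two numerical guards
   matter: the local scale is floored by a column-wide scale estimated
   from first differences (`1.4826/sqrt(2) * median|diff(x)|`), because in
   steep signal regions the running median returns the center sample and
   the local MAD collapses to zero, which would flag smooth curvature as
   spikes. The defaults are deliberately conservative — at T = 128 only
   gross outliers should be interpolated.
3. **Low-pass** — fifth-order Butterworth with 0.15 Hz cutoff, applied
   forward and backward (zero phase) so windowed correlations are not
   phase-distorted. Edges are handled by odd-reflection padding of
   `3 * (order + 1)` samples and by subtracting the end value before each
   causal pass, which removes the zero-state step transient of the IIR
   filter; DC is preserved to machine precision. Because the magnitude
   response is applied twice, the gain at the cutoff is 1/2 rather than
   1/sqrt(2). The cutoff must lie below Nyquist = 1/(2 TR); at TR = 3 s
   that is about 0.167 Hz.

### Tapered sliding windows and regularized connectivity

Window weights are a rectangle of `width` TR (default 22, i.e. 66 s)
convolved with a Gaussian of `sigma` = 3 TR, truncated to the central
`width` samples and normalized to sum 1. Truncation to exactly `width`
samples is intentional: it makes the window count equal
`T - width + 1` (107 windows for T = 128), matching the bookkeeping of the
windowed analysis this package implements. Windows move in steps of 1 TR;
a sweep over widths 18-28 TR is supported for robustness analyses.

Within each window a weighted covariance is formed (weighted mean removed,
weights summing to one) and regularized by the **graphical LASSO**: the
precision matrix maximizes `log det(Theta) - tr(S Theta) - lambda *
||Theta||_1` with the penalty on off-diagonal entries only. This is
implemented as block coordinate descent in C++ (each row/column update is
an L1-penalized quadratic solved by coordinate descent); the tests verify
it against an independent proximal-gradient maximizer and against the
analytic special cases (diagonal input, full-sparsity threshold, the
`lambda -> 0` limit).

The penalty is chosen **per subject** by cross-validation over windows:
windows are partitioned into contiguous fold blocks (contiguous rather
than interleaved, because adjacent windows share up to 21 of 22 samples
and interleaved folds would leak training samples into the test folds);
for each fold and candidate penalty, a model is fitted to the averaged
training-window covariance and scored by the mean Gaussian log-likelihood
of the held-out windows' sample covariances. The default grid is 30
log-spaced values in [1e-3, 1] with 20 folds.

Regularized covariances are converted to correlations and Fisher
z-transformed (`z = atanh(r)`, diagonal excluded). The z values are then
**residualized** with respect to age, gender and study membership: for
every connection pair and window index, a linear model across subjects on
the centered covariates is fitted and the residual plus intercept is kept,
so the covariate contribution is removed while the grand level — which
carries the state information used by clustering — is retained. Gender
and study are coded 0/1.

Temporal variability is the SD of each pair's z series over windows
(denominator W - 1), summarized per network (mean over its N - 1 partners)
and overall (mean over the N(N-1)/2 pairs). The SD is computed on the z
scale, which follows the transform step of the processing chain; computing
it on r instead is possible by transforming back before the call.

### Connectivity states

All subjects' windows are stacked into a feature matrix (rows =
subject-window pairs, columns = upper-triangle z values) and clustered by
**k-means under the Manhattan (L1) distance**: assignment to the nearest
centroid with ties to the lowest index, centroid update by the
componentwise median (the exact minimizer of summed L1 distance), 500
random restarts by default, convergence when assignments stop changing
(cap 100 iterations). Clusters that empty mid-iteration are re-seeded at
the row currently farthest from its centroid. Features are the
residualized z values by default (raw covariances can be clustered by
passing them instead); no exemplar-window subsampling is performed — all
windows of all subjects enter the clustering directly.

The number of states is chosen by the **elbow criterion** on the cluster
validity index (mean within-cluster distance over mean pairwise
between-centroid distance), evaluated for k = 2..8: the selected k
maximizes the perpendicular distance of the validity curve from the chord
joining its endpoints; an exactly linear curve has no elbow and is
reported as such. For reporting, states are relabeled by descending
assignment count so that "the most common state" is comparable across
runs.

Per-subject dynamics metrics from the assignment sequences: state
frequency (proportion of windows), mean dwell time (mean maximal-run
length per state, with runs touching the scan boundaries included — at
107 windows the truncation bias of excluding them would be larger than
the bias of keeping them), intertransition interval (mean run length over
all runs, `W / (transitions + 1)`) and number of transitions. Stability of
the states is assessed by split-half resampling (cluster each half of the
subjects, match centroids one-to-one by greedy maximal correlation) and by
bootstrap over subjects against the full-data centroids.

### Time-resolved graph efficiency

Each window's |z| matrix is binarized at fixed edge densities: exactly
`m = round(density * N(N-1)/2)` strongest edges are kept (rank-based
thresholding guarantees the target density; ties at the cutoff break
deterministically by row/column order). The default grid is every integer
edge count from 13 to 138 on 27 nodes, i.e. densities 3.7% to 39.3% — the
range is prescribed, the unit step is our choice since no step is
prescribed, and the grid is fully configurable. Absolute values are
thresholded; |r| and |z| rank identically, so the choice of scale does not
affect the graphs. Global efficiency is the mean inverse shortest-path
length over ordered pairs (disconnected pairs contribute 0; no
largest-component restriction); local efficiency of a node is the global
efficiency of its neighbor-induced subgraph, 0 for nodes with fewer than
two neighbors. Distances come from a vectorized all-pairs BFS (boolean
adjacency powers), cross-checked in the tests against Floyd-Warshall and
igraph. Per window, efficiencies are averaged over the density grid
(arithmetic mean as the discrete integral); their SD over windows is the
dynamic summary, and a static counterpart uses the whole-time-course
correlation matrix.

### Group statistics

Omnibus multivariate group effects use a **rank-permutation MANOVA**: each
column is midrank-transformed, the Pillai trace of the one-way group
effect is computed on ranks, and significance comes from label
permutations (`p = (1 + #{perm >= obs}) / (nPerm + 1)`). The citation
behind the published analysis does not pin down a specific variant, so
this permutation construction is the package's own declared choice,
validated by type-I calibration (about 5% rejections at the 5% level over
1000 null simulations) rather than by matching any published F statistic.
Since the total rank SSCP is permutation-invariant it is factored once;
compositional inputs (frequencies summing to 1) make it singular, in which
case a pseudoinverse is used.

Univariate follow-ups are Kruskal-Wallis tests with Dunn's pairwise
post-hocs (pooled midranks, tie-corrected), Benjamini-Hochberg FDR within
the pairwise family of one measure, and `r^2 = (z / sqrt(n))^2` effect
sizes. Clinical associations use midrank Spearman correlations with
pairwise-complete missing-data handling. Medication subgroup comparisons
use Mann-Whitney U (exact p for small tie-free samples, tie-corrected
normal approximation otherwise; U reported in the minimum orientation).
Demographic tables use Pearson chi-square without continuity correction
(the convention that reproduces the published cohort table), pooled-variance
t-tests computable from summary statistics (df = n1 + n2 - 2), and one-way
ANOVA from group summaries.

## The synthetic cohort generator

Because the patient fMRI data are not public, the package ships a
generator that emulates the *statistical structure* the analysis assumes:
a hidden-Markov switching process over a small set of covariance states
with zero-mean Gaussian emissions, plus polynomial trends, random additive
spikes and white noise to exercise the postprocessing stage. States switch
instantaneously at TR resolution. State covariances are correlation-scale
(unit diagonal) signed block matrices: a "strong" state with tight,
coupled visual/motor-like modules and anti-correlated blocks, a "sparse"
state with weak structure, and further states occupying rotated module
pairs so each state has its own connection topology. Patterns are shrunk
toward the identity only as far as needed to keep the smallest eigenvalue
at 0.1, which guarantees positive definiteness with controllable
separation.

Group effects are encoded **only through the Markov specification**
(occupancy and dwell), not through the emission covariances — this
isolates the dynamics effects the analysis is meant to detect. The default
cohort reproduces the study structure: 31 controls / 29 AD / 31 DLB
subjects, T = 128 at TR = 3 s, three states, transition matrices of the
form `(1 - a) I + a 1 pi'` whose stationary distribution is exactly `pi`;
controls are roughly balanced (`pi = (0.34, 0.40, 0.26)`) while the
patient groups shift mass from the strong state to the sparse state (AD
`(0.20, 0.52, 0.28)`, DLB `(0.14, 0.60, 0.26)`), keeping the sparse state
the most common overall. The switch rate default of 0.25 per TR gives mean
dwell times of a few TR. No quantitative separation scale is prescribed by
the study, so separation strength is a free scenario parameter.

What the generator does *not* emulate: hemodynamic autocorrelation,
scanner noise spectra, motion, spatial structure, and non-Gaussian
marginals of real network time courses. Tests passing on this generator
therefore demonstrate correctness of the estimation machinery under its
own assumptions, not robustness to every property of real fMRI data.

### Recovery scenario

The end-to-end recovery check runs the full pipeline (postprocessing,
tapered windows, cross-validated graphical LASSO, Fisher z,
residualization, L1 k-means) on 30 subjects with three well-separated
states and asks for at least 90% window-label accuracy after optimal label
permutation, and for the elbow to select k = 3. Three scenario choices are
forced by identifiability, not tuned. First, the mean dwell time must
comfortably exceed the 22-TR window (switch rate 0.01, mean dwell about
150 TR), otherwise many windows straddle transitions and window-level
labels are not defined by any method. Second, the states must differ in
pattern, not just scale (rotated module blocks at strength 0.9,
`sparseState = NA`), because two states that are scalar multiples of each
other are separated by less than the sampling noise of a 22-sample
covariance. Third, the states must be roughly *equidistant*: the validity
index divides by the mean pairwise centroid distance, so if one state is
far from two mutually close states, the k = 2 denominator (the single
largest separation) is inflated and the curve cannot bend at the true k —
a property of the index, not of the estimator. With equidistant strong
states the curve shows the expected steep drop to k = 3 and flattens
beyond it. Ground-truth window labels are the taper-weighted majority
state within each window.

The replicated detection check (two groups of 30 differing only in the
strong state's self-transition probability, Kruskal-Wallis + Dunn with
FDR on state-1 frequency/dwell) simulates the assignment sequences
directly from the group Markov models: the replication loop measures the
statistics' power and null calibration, while the estimation path is
covered by the single full-pipeline recovery run. Running the windowed
estimation inside every replicate would add nothing to what either check
establishes separately.

## Problem sizes and numerical choices

The shipped test-suite and acceptance scenarios use: 30-subject cohorts at
T = 128, N = 27 for recovery (penalty grid of 6 log-spaced values in
[0.01, 0.5] with 10 folds, 50 k-means restarts, 20 restarts in the k
sweep); 20 replicates for detection power and 1000 for null calibration;
1000 null simulations with 199 permutations each for MANOVA calibration.
Module-level tests use smaller fixtures (6 networks, 40-60 time points)
with brute-force oracles. Determinism: every stochastic routine takes a
seed; the cohort generator is deterministic given its spec seed, and the
pipeline records the seed in every output.

Further numerical details, in one place: taper weights are symmetrized
against convolution round-off; the graphical-LASSO convergence threshold
is relative to the mean absolute off-diagonal of S, with a 1e-10 ridge on
the working covariance for rank-deficient window estimates (22 samples,
27 variables); Fisher z errors out on |r| = 1; k-means ties go to the
lowest centroid index so runs are reproducible; the elbow is declared
absent when all chord distances are below 1e-10 of the curve scale;
density thresholds below one edge are an error rather than an empty
graph.

## Limitations

The MANOVA variant is a declared substitute (calibrated, not
literature-matched); dwell-time estimates at 107 windows are coarse for
slow chains; the generator's white-in-time emissions make windowed
covariance estimates somewhat better behaved than hemodynamically smoothed
data; and clinical-correlation analyses are implemented but can only be
exercised on synthetic scores. Published group-level effect sizes from the
original patient cohorts cannot be reproduced without the (unreleased)
patient data; all quantitative checks here are either desk-scale
arithmetic, published summary-statistic recomputations, or property-based
checks on synthetic cohorts.
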