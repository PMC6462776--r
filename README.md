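# dfcstates

Dynamic functional connectivity (dFC) analysis for brain-network time
courses, with a focus on dementia cohorts. Static connectivity studies
summarize each network pair by one correlation per scan; `dfcstates`
analyzes how between-network coupling reorganizes *within* a scan and
whether those dynamics differ between groups (e.g. healthy controls,
Alzheimer's disease, dementia with Lewy bodies).

The pipeline, starting from per-subject T x N network time courses in TSV
files:

1. **Postprocessing** — polynomial detrending (orders 1-3), robust
   despiking with cubic-spline interpolation, zero-phase fifth-order
   Butterworth low-pass at 0.15 Hz.
2. **Sliding-window connectivity** — a tapered window (22-TR rectangle
   convolved with a 3-TR Gaussian, step 1 TR; 107 windows for T = 128),
   weighted covariance per window, **graphical-LASSO** regularization
   (precision matrix maximizing `log det Θ − tr(SΘ) − λ‖Θ‖₁` off-diagonal)
   with the penalty λ chosen per subject by 20-fold cross-validation over
   windows, Fisher r-to-z, and residualization of z against age, gender
   and study membership. Temporal variability = SD of z over windows.
3. **Connectivity states** — k-means with Manhattan (L1) distance over all
   windows of all subjects (componentwise-median centroids, 500 restarts),
   k chosen by the elbow of the within/between cluster-validity ratio over
   k = 2..8; per-subject state frequency, mean dwell time, intertransition
   interval and transition counts; split-half and bootstrap stability.
4. **Dynamic network topology** — per-window binarized graphs at edge
   densities 3.7%-39.3% (rank-based thresholding of |z|), global and local
   efficiency averaged over the density grid, and their SD over time, plus
   a static whole-time-course counterpart.
5. **Group statistics** — rank-permutation MANOVA (Pillai trace on
   ranks), Kruskal-Wallis with Dunn post-hocs and Benjamini-Hochberg FDR,
   `r² = (z/√n)²` effect sizes, Spearman clinical correlations,
   Mann-Whitney U, and chi-square / pooled-t / one-way-ANOVA demographics
   from summary statistics.

Because the study's patient fMRI data are not public, the package includes
a **synthetic cohort generator**: hidden-Markov switching between
correlation-scale covariance states (zero-mean Gaussian emissions), with
group differences encoded through state occupancy, plus trends, spikes and
noise — with full ground truth, so state recovery and statistical power
can be tested end to end. See the vignette
`vignettes/dynamic-connectivity-states.Rmd` for the models, parameter
choices and limitations.

## Worked example

```r
library(dfcstates)

# a synthetic 91-subject cohort with the default three-group structure
spec <- defaultCohortSpec(seed = 1)
co <- simulateCohort(spec)
table(co$manifest$group)
#>  AD DLB  HC
#>  29  31  31

tc <- co$timecourses[["HC01"]]
tc
#> TimecourseSet 'HC01': 128 time points x 27 networks, TR = 3 s

# clean, window, regularize, z-transform one subject
pp <- postprocess(tc)
conn <- subjectConnectivity(pp$timecourse, makeTaper(), lambda = 0.1)
conn$z
#> WindowedConnectivity 'HC01': 107 windows of 27x27, stage 'z', lambda 0.1

# temporal variability of connectivity for this subject
connectivityVariability(conn$z)$overallMean
#> [1] 0.177

# ground-truth state dynamics of the same subject, projected onto windows
m <- stateMetrics(windowStateLabels(co$truth[["HC01"]]$states, makeTaper()), 3)
round(m$frequency, 3)
#> [1] 0.364 0.252 0.383

demographicsTable(co$manifest)
#>   variable          test statistic df     p
#> 1   gender    chi-square      1.56  2 0.458
#> 2    study    chi-square      3.02  2 0.221
#> 3      age one-way ANOVA      1.27 88 0.287
```

The 107 windows are `128 − 22 + 1`: the tapered window spans 22 TR and
moves in steps of 1 TR. The overall mean SD (0.177) is the subject's
whole-brain dFC variability — the mean over all 351 network pairs of the
SD of Fisher z across the 107 windows. The frequencies are the fraction of
windows this subject spends in each latent connectivity state.

For a cohort-level run (all five stages, with outputs written to disk):

```r
res <- runPipeline(co$timecourses, co$manifest,
                   runConfig(k = 3, nInit = 100, seed = 1),
                   outDir = "results/run1")
res$states$metrics      # per-subject frequency / dwell / transitions
res$stats$stateTests    # Kruskal-Wallis + Dunn (FDR) group comparisons
```

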