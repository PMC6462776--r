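Package: dfcstates
Title: Dynamic Functional Connectivity States from Network Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Sliding-window dynamic functional connectivity analysis for
    per-subject brain-network time courses: polynomial detrending, despiking
    and zero-phase low-pass filtering; tapered-window covariance with
    graphical-LASSO regularization and per-subject cross-validated penalty
    selection; Fisher z transformation and covariate residualization;
    Manhattan-distance k-means connectivity states with elbow-based model
    selection, dwell-time/frequency/transition metrics and resampling
    stability; time-resolved binarized-graph global and local efficiency over
    edge-density grids; and non-parametric group statistics (rank-permutation
    MANOVA, Kruskal-Wallis with Dunn/FDR post-hocs, effect sizes, clinical
    correlations). Includes a hidden-Markov synthetic cohort generator with
    full ground truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    MASS,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
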