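#' Kruskal-Wallis rank test
#'
#' Midrank-based H with tie correction and chi-square p-value
#' (df = number of groups - 1). Identical values across all groups give
#' H = 0, p = 1.
#'
#' @param groups list of numeric vectors (>= 2 nonempty groups).
#' @return list with `H`, `df`, `p`.
#' @export
kruskalWallis <- function(groups) {
  stopifnot(length(groups) >= 2, all(lengths(groups) > 0))
  if (length(unique(unlist(groups))) == 1)
    return(list(H = 0, df = length(groups) - 1L, p = 1))
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = unname(kt$p.value))
}

#' Dunn's post-hoc test with FDR adjustment
#'
#' Pairwise z statistics from the pooled midranks with tie correction,
#' two-sided normal p-values, and Benjamini-Hochberg adjustment across the
#' pairwise family by default.
#'
#' @param groups named list of numeric vectors.
#' @param method p-adjustment method (see [stats::p.adjust()]).
#' @return data.frame with `group1`, `group2`, `z`, `p`, `p.adj`.
#' @export
dunnPosthoc <- function(groups, method = "BH") {
  g <- length(groups)
  stopifnot(g >= 2)
  if (any(lengths(groups) == 0)) stop("all groups must be nonempty")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(g))
  x <- unlist(groups, use.names = FALSE)
  n <- length(x)
  rk <- rank(x)
  sizes <- lengths(groups)
  idx <- rep(seq_len(g), sizes)
  meanRank <- tapply(rk, idx, mean)
  ties <- table(x)
  tieTerm <- sum(ties^3 - ties)
  varTerm <- n * (n + 1) / 12 - tieTerm / (12 * (n - 1))
  pairs <- utils::combn(g, 2)
  z <- p <- numeric(ncol(pairs))
  for (c in seq_len(ncol(pairs))) {
    i <- pairs[1, c]; j <- pairs[2, c]
    se <- sqrt(varTerm * (1 / sizes[i] + 1 / sizes[j]))
    z[c] <- if (se > 0) (meanRank[i] - meanRank[j]) / se else 0
    p[c] <- 2 * stats::pnorm(-abs(z[c]))
  }
  data.frame(group1 = names(groups)[pairs[1, ]],
             group2 = names(groups)[pairs[2, ]],
             z = z, p = p, p.adj = stats::p.adjust(p, method = method),
             stringsAsFactors = FALSE)
}

# Pillai trace of a one-way layout: tr(H (H + E)^-1), with H + E the total
# centered SSCP (invariant under label permutation)
pillaiTrace <- function(Y, groupIdx, Tinv) {
  gm <- rowsum(Y, groupIdx)
  ng <- tabulate(groupIdx)
  means <- gm / ng
  center <- colMeans(Y)
  dev <- sweep(means, 2, center)
  H <- crossprod(dev * sqrt(ng), dev * sqrt(ng))
  sum(diag(H %*% Tinv))
}

#' Rank-permutation multivariate group test (Pillai trace on ranks)
#'
#' Columns are rank-transformed (midranks); the Pillai trace of the one-way
#' group effect is computed on the ranks and its significance assessed by
#' random permutation of group labels:
#' `p = (1 + #permuted >= observed) / (nPerm + 1)`.
#'
#' @param data subjects x variables numeric matrix or data.frame.
#' @param groups group label per subject.
#' @param nPerm number of permutations (default 9999).
#' @param seed RNG seed.
#' @return list with `statistic` (observed Pillai trace on ranks), `p`,
#'   `nPerm`.
#' @export
nonparametricManova <- function(data, groups, nPerm = 9999, seed = 1) {
  Y <- as.matrix(data)
  stopifnot(nrow(Y) == length(groups), ncol(Y) >= 1)
  constant <- which(apply(Y, 2, function(v) length(unique(v)) == 1))
  if (length(constant))
    stop("constant column(s): ",
         paste(colnames(Y)[constant] %||% constant, collapse = ", "))
  groups <- as.factor(groups)
  if (nrow(Y) < ncol(Y) + nlevels(groups))
    stop("need at least variables + groups subjects")
  R <- apply(Y, 2, rank)
  Rc <- sweep(R, 2, colMeans(R))
  Tot <- crossprod(Rc)
  # pseudoinverse tolerates collinear columns (e.g. compositional frequencies)
  Tinv <- tryCatch(solve(Tot), error = function(e) MASS::ginv(Tot))
  gidx <- as.integer(groups)
  obs <- pillaiTrace(R, gidx, Tinv)
  set.seed(seed)
  n <- nrow(R)
  count <- 0L
  for (b in seq_len(nPerm)) {
    perm <- pillaiTrace(R, gidx[sample.int(n)], Tinv)
    if (perm >= obs - 1e-12) count <- count + 1L
  }
  list(statistic = obs, p = (1 + count) / (nPerm + 1), nPerm = nPerm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' r-squared effect size from a standardized statistic
#'
#' For a pairwise rank test, `r = z / sqrt(n)` over the n observations of
#' the two groups compared; returns `r^2`.
#'
#' @param z standardized test statistic.
#' @param n total number of observations in the comparison.
#' @return r-squared in \[0, 1\].
#' @export
effectSizeR2 <- function(z, n) {
  if (n <= 0) stop("n must be positive")
  (z / sqrt(n))^2
}

#' Spearman correlations between dynamic measures and clinical scores
#'
#' Midrank Spearman correlations with pairwise-complete handling of missing
#' values; optional FDR adjustment across the family.
#'
#' @param measures data.frame of dynamic connectivity measures.
#' @param clinical data.frame of clinical scores (same subjects/rows).
#' @param adjust logical; add BH-adjusted p-values across all pairs.
#' @return data.frame with `measure`, `clinical`, `rho`, `p`, `n`
#'   (and `p.adj`).
#' @export
spearmanClinical <- function(measures, clinical, adjust = TRUE) {
  stopifnot(nrow(measures) == nrow(clinical))
  out <- list()
  for (m in names(measures)) for (cl in names(clinical)) {
    x <- measures[[m]]; y <- clinical[[cl]]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3)
      stop(sprintf("fewer than 3 complete pairs for (%s, %s)", m, cl))
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      stop(sprintf("zero variance in (%s, %s)", m, cl))
    ct <- suppressWarnings(
      stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
    out[[length(out) + 1L]] <- data.frame(
      measure = m, clinical = cl, rho = unname(ct$estimate),
      p = ct$p.value, n = sum(ok), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (adjust) res$p.adj <- stats::p.adjust(res$p, method = "BH")
  res
}

#' Mann-Whitney U test
#'
#' Midrank U statistic reported in the minimum orientation. The p-value is
#' exact (by enumeration of the null distribution) for small tie-free
#' samples, otherwise a normal approximation with tie correction is used.
#'
#' @param a,b numeric vectors.
#' @param exactMax use exact p when both groups are <= this size and tie-free.
#' @return list with `U`, `p`, `z` (normal-approximation z).
#' @export
mannWhitneyU <- function(a, b, exactMax = 50) {
  stopifnot(length(a) > 0, length(b) > 0)
  na <- length(a); nb <- length(b)
  rk <- rank(c(a, b))
  Ua <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  Ub <- na * nb - Ua
  U <- min(Ua, Ub)
  hasTies <- anyDuplicated(c(a, b)) > 0
  mu <- na * nb / 2
  ties <- table(c(a, b))
  n <- na + nb
  sigma <- sqrt(na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1))))
  z <- if (sigma > 0) (Ua - mu) / sigma else 0
  if (!hasTies && na <= exactMax && nb <= exactMax) {
    p <- stats::pwilcox(U, na, nb) + (1 - stats::pwilcox(Ub - 1, na, nb))
    p <- min(1, p)
  } else {
    p <- if (sigma > 0) 2 * stats::pnorm(-abs(z)) else 1
  }
  list(U = unname(U), p = unname(p), z = unname(z))
}

#' Pearson chi-square test from a contingency table
#'
#' No continuity correction. A warning is logged (not an error) when an
#' expected cell count falls below 1.
#'
#' @param counts matrix of counts.
#' @return list with `statistic`, `df`, `p`.
#' @export
chiSquareCounts <- function(counts) {
  counts <- as.matrix(counts)
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected < 1)) warning("expected cell count below 1")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' Two-sample pooled-variance t-test from summary statistics
#'
#' Student's t with df = n1 + n2 - 2, computed from group means, standard
#' deviations and sizes.
#'
#' @param mean1,sd1,n1 first group summaries.
#' @param mean2,sd2,n2 second group summaries.
#' @return list with `t`, `df`, `p`.
#' @export
tTestSummary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' One-way ANOVA from summary statistics
#'
#' @param means,sds,ns group means, standard deviations and sizes.
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
anovaSummary <- function(means, sds, ns) {
  k <- length(means)
  stopifnot(k >= 2, length(sds) == k, length(ns) == k, all(ns >= 2))
  N <- sum(ns)
  grand <- sum(ns * means) / N
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((ns - 1) * sds^2)
  df1 <- k - 1
  df2 <- N - k
  F <- (ssb / df1) / (ssw / df2)
  list(F = F, df1 = df1, df2 = df2, p = stats::pf(F, df1, df2, lower.tail = FALSE))
}

#' Demographics comparison table from a subject manifest
#'
#' Chi-square tests (no continuity correction) for gender and study
#' composition across groups, and a one-way ANOVA for age.
#'
#' @param manifest data.frame with `group`, `gender`, `study`, `age`.
#' @return data.frame with one row per test: `variable`, `test`,
#'   `statistic`, `df`, `p`.
#' @export
demographicsTable <- function(manifest) {
  stopifnot(all(c("group", "gender", "study", "age") %in% names(manifest)))
  rows <- list()
  for (v in c("gender", "study")) {
    cs <- chiSquareCounts(table(manifest[[v]], manifest$group))
    rows[[v]] <- data.frame(variable = v, test = "chi-square",
                            statistic = cs$statistic, df = cs$df, p = cs$p,
                            stringsAsFactors = FALSE)
  }
  grp <- split(manifest$age, manifest$group)
  av <- anovaSummary(vapply(grp, mean, 1), vapply(grp, stats::sd, 1),
                     lengths(grp))
  rows$age <- data.frame(variable = "age", test = "one-way ANOVA",
                         statistic = av$F, df = av$df2, p = av$p,
                         stringsAsFactors = FALSE)
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Kruskal-Wallis + Dunn (FDR) group comparison of state metrics
#'
#' Runs the Kruskal-Wallis test and Dunn's FDR-corrected post-hocs for each
#' metric column, with r-squared effect sizes per pairwise comparison.
#'
#' @param metrics data.frame from [cohortStateMetrics()] (or any per-subject
#'   measures) with a `subject` column.
#' @param groups group label per row of `metrics`.
#' @param columns metric columns to test (default: all numeric columns).
#' @return list with `omnibus` (per-column H, df, p) and `pairwise`
#'   (per-column Dunn results with `r2`).
#' @export
compareGroups <- function(metrics, groups, columns = NULL) {
  stopifnot(nrow(metrics) == length(groups))
  if (is.null(columns))
    columns <- names(metrics)[vapply(metrics, is.numeric, TRUE)]
  omnibus <- list()
  pairwise <- list()
  for (cn in columns) {
    v <- metrics[[cn]]
    ok <- !is.na(v)
    byGroup <- split(v[ok], groups[ok])
    byGroup <- byGroup[lengths(byGroup) > 0]
    if (length(byGroup) < 2) next
    kw <- kruskalWallis(byGroup)
    omnibus[[cn]] <- data.frame(measure = cn, H = kw$H, df = kw$df, p = kw$p,
                                stringsAsFactors = FALSE)
    dn <- dunnPosthoc(byGroup)
    sizes <- lengths(byGroup)
    dn$r2 <- mapply(function(z, g1, g2) effectSizeR2(z, sizes[g1] + sizes[g2]),
                    dn$z, dn$group1, dn$group2)
    dn$measure <- cn
    pairwise[[cn]] <- dn
  }
  list(omnibus = do.call(rbind, c(omnibus, list(make.row.names = FALSE))),
       pairwise = do.call(rbind, c(pairwise, list(make.row.names = FALSE))))
}
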