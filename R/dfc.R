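#' Tapered sliding-window weights
#'
#' Builds the window weight profile by convolving a rectangle of `width`
#' samples with a discrete unit-area Gaussian kernel of standard deviation
#' `sigma` (both in TR units), keeping the central `width` samples and
#' renormalizing to sum 1. As `sigma -> 0` the taper tends to the uniform
#' window.
#'
#' @param width window width in TR (default 22).
#' @param sigma Gaussian sd in TR (default 3).
#' @param step window step in TR (default 1).
#' @return list of class `TaperSpec` with `weights`, `width`, `sigma`, `step`.
#' @export
makeTaper <- function(width = 22, sigma = 3, step = 1) {
  stopifnot(sigma > 0, step >= 1)
  if (width < 2) stop("window width must be at least 2 TR")
  K <- max(1L, ceiling(6 * sigma))
  g <- stats::dnorm(seq(-K, K), sd = sigma)
  g <- g / sum(g)
  full <- stats::convolve(rep(1, width), rev(g), type = "open")
  wts <- full[(K + 1):(K + width)]
  wts <- wts / sum(wts)
  # enforce exact symmetry against convolution round-off
  wts <- (wts + rev(wts)) / 2
  structure(list(weights = wts, width = as.integer(width),
                 sigma = sigma, step = as.integer(step)),
            class = "TaperSpec")
}

#' Number of sliding windows
#'
#' `floor((T - width) / step) + 1`; e.g. 128 time points with a 22-TR window
#' at step 1 give 107 windows.
#'
#' @param T number of time points.
#' @param width window width in TR.
#' @param step window step in TR.
#' @return integer window count.
#' @export
windowCount <- function(T, width, step = 1) {
  if (T < width)
    stop(sprintf("time course too short: T = %d < window width %d", T, width))
  as.integer(floor((T - width) / step) + 1)
}

#' Tapered windowed sample covariance
#'
#' For each window, computes the weighted sample covariance using the taper
#' weights (weighted mean removed per window; weights sum to 1).
#'
#' @param tc a (postprocessed) [TimecourseSet-class].
#' @param taper a `TaperSpec` from [makeTaper()].
#' @return A [WindowedConnectivity-class] at stage `"covariance"`.
#' @export
windowedCovariance <- function(tc, taper) {
  stopifnot(is(tc, "TimecourseSet"), inherits(taper, "TaperSpec"))
  X <- tcData(tc)
  T <- nrow(X)
  N <- ncol(X)
  w <- taper$width
  W <- windowCount(T, w, taper$step)
  starts <- seq(1L, by = taper$step, length.out = W)
  wts <- taper$weights
  out <- array(0, dim = c(N, N, W))
  for (i in seq_len(W)) {
    seg <- X[starts[i]:(starts[i] + w - 1), , drop = FALSE]
    m <- colSums(seg * wts)
    xc <- sweep(seg, 2, m)
    out[, , i] <- crossprod(xc, xc * wts)
  }
  new("WindowedConnectivity", matrices = out, windowStarts = starts,
      stage = "covariance", lambda = NA_real_,
      subjectId = tc@subjectId, networkNames = tc@networkNames)
}

#' Graphical-LASSO precision and covariance estimate
#'
#' Maximizes `log det(Theta) - tr(S Theta) - lambda * ||Theta||_1` (penalty
#' on off-diagonal entries) by block coordinate descent; the returned
#' covariance is the inverse of the returned precision matrix.
#'
#' @param S symmetric sample covariance with positive diagonal.
#' @param lambda L1 penalty (>= 0).
#' @param maxIter outer iteration cap.
#' @param tol convergence tolerance (relative to mean |off-diagonal| of S).
#' @return list with `precision`, `covariance`, `iterations`.
#' @export
graphicalLasso <- function(S, lambda, maxIter = 200, tol = 1e-6) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S) || max(abs(S - t(S))) > 1e-8)
    stop("S must be symmetric")
  if (lambda < 0) stop("lambda must be nonnegative")
  S <- (S + t(S)) / 2
  fit <- glasso_cpp(S, lambda, maxit = maxIter, tol = tol)
  if (!fit$converged)
    stop(sprintf("graphical LASSO did not converge at lambda = %g after %d iterations",
                 lambda, fit$iterations))
  list(precision = fit$theta, covariance = fit$w, iterations = fit$iterations)
}

#' Default log-spaced penalty grid
#' @param n grid size.
#' @param min,max grid range (strictly positive).
#' @return increasing numeric vector.
#' @export
lambdaGrid <- function(n = 30, min = 1e-3, max = 1) {
  stopifnot(min > 0, max > min, n >= 1)
  exp(seq(log(min), log(max), length.out = n))
}

#' Cross-validated penalty selection for one subject
#'
#' Partitions the subject's windows into `nFolds` contiguous blocks. For
#' each fold and each candidate penalty, a graphical LASSO is fitted to the
#' pooled (averaged) training-window covariance, and scored by the mean
#' Gaussian log-likelihood of the held-out windows' sample covariances under
#' the fitted model. The chosen penalty maximizes the mean held-out
#' log-likelihood across folds.
#'
#' @param wc a [WindowedConnectivity-class] at stage `"covariance"`.
#' @param grid candidate penalties (default [lambdaGrid()]).
#' @param nFolds number of folds (default 20).
#' @param maxIter,tol passed to [graphicalLasso()].
#' @return list with `lambda` (chosen), `grid`, `scores` (folds x grid) and
#'   `meanScores`.
#' @export
selectLambda <- function(wc, grid = lambdaGrid(), nFolds = 20,
                         maxIter = 200, tol = 1e-6) {
  stopifnot(is(wc, "WindowedConnectivity"), wc@stage == "covariance")
  W <- nWindows(wc)
  if (W < nFolds)
    stop(sprintf("only %d windows for %d folds; use a smaller nFolds", W, nFolds))
  p <- length(wc@networkNames)
  mats <- wc@matrices
  foldId <- as.integer(cut(seq_len(W), breaks = nFolds, labels = FALSE))
  scores <- matrix(NA_real_, nFolds, length(grid))
  for (f in seq_len(nFolds)) {
    train <- which(foldId != f)
    test <- which(foldId == f)
    Strain <- apply(mats[, , train, drop = FALSE], c(1, 2), mean)
    for (l in seq_along(grid)) {
      fit <- graphicalLasso(Strain, grid[l], maxIter = maxIter, tol = tol)
      ld <- determinant(fit$precision, logarithm = TRUE)$modulus
      ll <- vapply(test, function(i) {
        0.5 * (as.numeric(ld) - sum(mats[, , i] * fit$precision) -
                 p * log(2 * pi))
      }, numeric(1))
      scores[f, l] <- mean(ll)
    }
  }
  meanScores <- colMeans(scores)
  list(lambda = grid[which.max(meanScores)], grid = grid,
       scores = scores, meanScores = meanScores)
}

#' Regularize window covariances with the graphical LASSO
#'
#' @param wc a [WindowedConnectivity-class] at stage `"covariance"`.
#' @param lambda penalty applied to every window.
#' @param maxIter,tol passed to [graphicalLasso()].
#' @return A [WindowedConnectivity-class] at stage `"regularized"` holding
#'   the estimated covariances.
#' @export
regularizeWindows <- function(wc, lambda, maxIter = 200, tol = 1e-6) {
  stopifnot(is(wc, "WindowedConnectivity"), wc@stage == "covariance")
  out <- wc@matrices
  for (i in seq_len(nWindows(wc)))
    out[, , i] <- graphicalLasso(wc@matrices[, , i], lambda,
                                 maxIter = maxIter, tol = tol)$covariance
  initialize(wc, matrices = out, stage = "regularized", lambda = lambda)
}

#' Fisher z connectivity matrices
#'
#' Converts each window's covariance to correlations
#' (`r_ij = c_ij / sqrt(c_ii c_jj)`) and applies the Fisher r-to-z transform
#' `z = atanh(r)`. Diagonals are set to 0 (excluded from analysis).
#'
#' @param wc a [WindowedConnectivity-class] at stage `"covariance"` or
#'   `"regularized"`.
#' @return A [WindowedConnectivity-class] at stage `"z"`.
#' @export
toFisherZ <- function(wc) {
  stopifnot(is(wc, "WindowedConnectivity"),
            wc@stage %in% c("covariance", "regularized"))
  out <- wc@matrices
  for (i in seq_len(nWindows(wc))) {
    C <- out[, , i]
    d <- diag(C)
    if (any(d <= 0))
      stop(sprintf("window %d: nonpositive variance for network %s",
                   i, paste(wc@networkNames[d <= 0], collapse = ", ")))
    r <- C / tcrossprod(sqrt(d))
    diag(r) <- 0
    bad <- which(abs(r) >= 1, arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("window %d: |r| = 1 for pair (%s, %s); Fisher z undefined",
                   i, wc@networkNames[bad[1, 1]], wc@networkNames[bad[1, 2]]))
    out[, , i] <- atanh(r)
  }
  initialize(wc, matrices = out, stage = "z")
}

#' Windowed connectivity for one subject (covariance to Fisher z)
#'
#' Convenience chain: tapered windowed covariance, per-subject penalty
#' selection by cross-validation (or a fixed penalty), graphical-LASSO
#' regularization of every window, and Fisher z transformation.
#'
#' @param tc a postprocessed [TimecourseSet-class].
#' @param taper a `TaperSpec`.
#' @param lambda fixed penalty, or `"cv"` to cross-validate.
#' @param grid,nFolds passed to [selectLambda()] when `lambda = "cv"`.
#' @return list with `z` ([WindowedConnectivity-class] at stage `"z"`),
#'   `lambda` and (when cross-validated) `selection`.
#' @export
subjectConnectivity <- function(tc, taper = makeTaper(), lambda = "cv",
                                grid = lambdaGrid(), nFolds = 20) {
  wc <- windowedCovariance(tc, taper)
  selection <- NULL
  if (identical(lambda, "cv")) {
    selection <- selectLambda(wc, grid = grid, nFolds = nFolds)
    lambda <- selection$lambda
  }
  reg <- regularizeWindows(wc, lambda)
  list(z = toFisherZ(reg), lambda = lambda, selection = selection)
}

# row-major upper-triangle index pairs for an N x N matrix
utPairs <- function(N) {
  idx <- which(upper.tri(matrix(0, N, N)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

# W x P matrix of upper-triangle features from an N x N x W array
utFeatures <- function(a) {
  N <- dim(a)[1]
  pairs <- utPairs(N)
  t(apply(a, 3, function(m) m[pairs]))
}

#' Residualize Fisher z values with respect to subject covariates
#'
#' For every connection pair and window index, fits across subjects a linear
#' model of z on the centered covariates plus intercept and keeps
#' `residual + intercept`, removing the covariate contribution while
#' retaining the grand level. Gender and study are coded 0/1; numeric
#' covariates are centered.
#'
#' @param zList named list of [WindowedConnectivity-class] at stage `"z"`,
#'   one per subject, with identical dimensions.
#' @param covariates data.frame with a `subject_id` column matching
#'   `names(zList)` plus covariate columns (default `age`, `gender`,
#'   `study`).
#' @param columns covariate columns to regress out.
#' @return named list of [WindowedConnectivity-class] at stage
#'   `"residualized"`.
#' @export
residualizeConnectivity <- function(zList, covariates,
                                    columns = c("age", "gender", "study")) {
  stopifnot(length(zList) >= 2, !is.null(names(zList)))
  ids <- names(zList)
  if (!all(ids %in% covariates$subject_id))
    stop("covariates missing for subjects: ",
         paste(setdiff(ids, covariates$subject_id), collapse = ", "))
  cov <- covariates[match(ids, covariates$subject_id), , drop = FALSE]
  X <- sapply(columns, function(cn) {
    v <- cov[[cn]]
    if (is.null(v)) stop(sprintf("covariate column '%s' not found", cn))
    if (!is.numeric(v)) v <- as.numeric(factor(v)) - 1
    v
  })
  X <- as.matrix(X)
  n <- length(ids)
  if (n < ncol(X) + 2)
    stop("need at least 2 more subjects than covariates")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  qrX <- qr(Xc)
  if (qrX$rank < ncol(Xc)) {
    drop <- columns[setdiff(seq_len(ncol(Xc)), qrX$pivot[seq_len(qrX$rank)])]
    stop("rank-deficient covariate design; collinear columns: ",
         paste(drop, collapse = ", "))
  }
  dims <- dim(zList[[1]]@matrices)
  N <- dims[1]
  W <- dims[3]
  pairs <- utPairs(N)
  # subjects x (pairs * windows) response matrix
  Y <- t(vapply(zList, function(z) {
    as.vector(apply(z@matrices, 3, function(m) m[pairs]))
  }, numeric(nrow(pairs) * W)))
  Yc <- sweep(Y, 2, colMeans(Y))
  B <- solve(crossprod(Xc), crossprod(Xc, Yc))
  R <- Y - Xc %*% B
  out <- zList
  for (i in seq_along(ids)) {
    a <- array(0, dim = dims)
    vals <- matrix(R[i, ], nrow = nrow(pairs), ncol = W)
    for (wdx in seq_len(W)) {
      m <- matrix(0, N, N)
      m[pairs] <- vals[, wdx]
      a[, , wdx] <- m + t(m)
    }
    out[[i]] <- initialize(zList[[i]], matrices = a, stage = "residualized")
  }
  out
}

#' Temporal variability (SD) of windowed connectivity
#'
#' Standard deviation over windows (denominator W - 1) of each connection,
#' the per-network mean SD across its N - 1 partners, and the overall mean
#' over the N(N-1)/2 unique pairs.
#'
#' @param wc a [WindowedConnectivity-class] with at least 2 windows
#'   (typically stage `"residualized"`).
#' @return list with `sdMatrix` (symmetric, zero diagonal), `networkMeans`
#'   and `overallMean`.
#' @export
connectivityVariability <- function(wc) {
  stopifnot(is(wc, "WindowedConnectivity"))
  W <- nWindows(wc)
  if (W < 2) stop("need at least 2 windows to compute an SD over time")
  a <- wc@matrices
  N <- dim(a)[1]
  sdMat <- apply(a, c(1, 2), stats::sd)
  diag(sdMat) <- 0
  dimnames(sdMat) <- list(wc@networkNames, wc@networkNames)
  networkMeans <- rowSums(sdMat) / (N - 1)
  overall <- mean(sdMat[upper.tri(sdMat)])
  list(sdMatrix = sdMat, networkMeans = networkMeans, overallMean = overall)
}
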