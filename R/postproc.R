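#' Remove polynomial trends from network time courses
#'
#' Projects each network's time course onto the orthogonal polynomial basis
#' up to `maxOrder` (plus intercept) and removes the fit, so the residual is
#' orthogonal to that basis. The default removes linear, quadratic and cubic
#' trends.
#'
#' @param tc a [TimecourseSet-class].
#' @param maxOrder highest polynomial order removed (default 3).
#' @return A detrended [TimecourseSet-class].
#' @export
detrendTimecourse <- function(tc, maxOrder = 3) {
  stopifnot(is(tc, "TimecourseSet"), maxOrder >= 0)
  X <- tcData(tc)
  T <- nrow(X)
  if (T <= maxOrder + 1)
    stop(sprintf("need more than %d time points to remove order-%d trends",
                 maxOrder + 1, maxOrder))
  basis <- cbind(1, stats::poly(seq_len(T), degree = maxOrder))
  Q <- qr.Q(qr(basis))
  R <- X - Q %*% crossprod(Q, X)
  dimnames(R) <- dimnames(X)
  initialize(tc, data = R)
}

#' Detect and interpolate outlier time points (despiking)
#'
#' Outliers are detected per network from the deviation of the signal to a
#' running median: a point is flagged when its absolute deviation exceeds
#' `madThreshold` times a robust local scale (running median absolute
#' deviation of the same window, scaled by 1.4826 and floored at a small
#' fraction of the column SD so smooth curvature is never flagged). Flagged
#' points are replaced by a cubic spline fitted through the clean points.
#'
#' @param tc a [TimecourseSet-class] (detrended input recommended).
#' @param madThreshold robust-deviation threshold (default 4).
#' @param medianWindow odd length of the running-median window (default 11).
#' @return list with `timecourse` (cleaned [TimecourseSet-class]) and
#'   `report` (per-network outlier counts and positions, settings).
#' @export
despikeTimecourse <- function(tc, madThreshold = 4, medianWindow = 11) {
  stopifnot(is(tc, "TimecourseSet"), madThreshold > 0)
  if (medianWindow %% 2 == 0) medianWindow <- medianWindow + 1
  X <- tcData(tc)
  T <- nrow(X)
  tgrid <- seq_len(T)
  outliers <- vector("list", ncol(X))
  names(outliers) <- colnames(X)
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    med <- stats::runmed(x, medianWindow, endrule = "med")
    d <- x - med
    # local robust scale, floored at a first-difference noise estimate: in
    # steep signal regions the running median returns the center sample and
    # deflates the local MAD, while |diff| is robust to slow trends and to
    # isolated spikes
    scale <- 1.4826 * stats::runmed(abs(d), medianWindow, endrule = "med")
    floorScale <- max(1.4826 / sqrt(2) * stats::median(abs(diff(x))), 1e-12)
    flagged <- which(abs(d) > madThreshold * pmax(scale, floorScale))
    outliers[[j]] <- flagged
    if (length(flagged)) {
      clean <- setdiff(tgrid, flagged)
      if (length(clean) < 4)
        stop(sprintf("network '%s': too few clean points to fit a cubic spline",
                     colnames(X)[j]))
      fit <- stats::splinefun(clean, x[clean], method = "fmm")
      X[flagged, j] <- fit(flagged)
    }
  }
  report <- list(
    outlierPositions = outliers,
    outlierCounts = vapply(outliers, length, integer(1)),
    madThreshold = madThreshold,
    medianWindow = medianWindow
  )
  list(timecourse = initialize(tc, data = X), report = report)
}

#' Zero-phase low-pass Butterworth filtering
#'
#' Applies a fifth-order (by default) low-pass Butterworth filter forward and
#' backward (zero phase), after odd-reflection padding of length
#' `3 * (order + 1)` samples at each end to suppress edge transients. DC is
#' preserved; the forward-backward pass squares the single-pass magnitude
#' response, so the gain at the cutoff frequency is 1/2 rather than
#' 1/sqrt(2).
#'
#' @param tc a [TimecourseSet-class].
#' @param cutoffHz cutoff frequency in Hz (must be below Nyquist = 1/(2 TR)).
#' @param order filter order (default 5).
#' @return A filtered [TimecourseSet-class].
#' @export
lowpassTimecourse <- function(tc, cutoffHz = 0.15, order = 5) {
  stopifnot(is(tc, "TimecourseSet"), cutoffHz > 0, order >= 1)
  nyquist <- 1 / (2 * tcTR(tc))
  if (cutoffHz >= nyquist)
    stop(sprintf("cutoff %.4g Hz is not below the Nyquist frequency %.4g Hz",
                 cutoffHz, nyquist))
  bf <- signal::butter(order, cutoffHz / nyquist, type = "low")
  dcGain <- sum(bf$b) / sum(bf$a)
  # single causal pass with the end-value subtracted first, so the zero-state
  # step transient of the IIR filter vanishes for the DC component
  onePass <- function(x) {
    as.numeric(signal::filter(bf, x - x[1])) + x[1] * dcGain
  }
  X <- tcData(tc)
  T <- nrow(X)
  np <- min(3 * (order + 1), T - 1)
  Y <- apply(X, 2, function(x) {
    # odd reflection about the end points
    pre <- 2 * x[1] - x[(np + 1):2]
    post <- 2 * x[T] - x[(T - 1):(T - np)]
    xp <- c(pre, x, post)
    fwd <- onePass(xp)
    bwd <- rev(onePass(rev(fwd)))
    bwd[(np + 1):(np + T)]
  })
  dimnames(Y) <- dimnames(X)
  initialize(tc, data = Y)
}

#' Full time-course postprocessing chain
#'
#' Runs detrend, despike and zero-phase low-pass filtering in that order.
#'
#' @param tc a [TimecourseSet-class].
#' @param maxOrder trend order for [detrendTimecourse()].
#' @param madThreshold,medianWindow despiking parameters.
#' @param cutoffHz,filterOrder low-pass parameters.
#' @return list with `timecourse` and the despiking `report`.
#' @export
postprocess <- function(tc, maxOrder = 3, madThreshold = 4, medianWindow = 11,
                        cutoffHz = 0.15, filterOrder = 5) {
  tc <- detrendTimecourse(tc, maxOrder)
  ds <- despikeTimecourse(tc, madThreshold, medianWindow)
  out <- lowpassTimecourse(ds$timecourse, cutoffHz, filterOrder)
  list(timecourse = out, report = ds$report)
}
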