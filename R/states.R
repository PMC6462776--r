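#' Stack subject window matrices into a feature matrix
#'
#' Rows are subject-window pairs (ordered by subject, then window); columns
#' are the N(N-1)/2 upper-triangle connection features in row-major order.
#'
#' @param wcList named list of [WindowedConnectivity-class] objects (one per
#'   subject, equal dimensions).
#' @return list with `features` (matrix) and `rowInfo` (data.frame with
#'   `subject` and `window`).
#' @export
connectivityFeatures <- function(wcList) {
  stopifnot(length(wcList) >= 1, !is.null(names(wcList)))
  feats <- lapply(wcList, function(wc) utFeatures(wc@matrices))
  features <- do.call(rbind, feats)
  rowInfo <- do.call(rbind, lapply(names(wcList), function(id) {
    data.frame(subject = id, window = seq_len(nrow(feats[[id]])),
               stringsAsFactors = FALSE)
  }))
  if (anyNA(features)) stop("feature matrix contains missing values")
  list(features = features, rowInfo = rowInfo)
}

#' k-means clustering under the Manhattan (L1) distance
#'
#' Lloyd iterations with assignment to the nearest centroid under the L1
#' metric (ties to the lowest centroid index) and centroid update by the
#' componentwise median, repeated for `nInit` random initializations
#' (centroids seeded at distinct random rows); the lowest-objective solution
#' is returned. Clusters that empty during iteration are re-seeded at the
#' row farthest from its assigned centroid.
#'
#' @param features numeric matrix, or the list from
#'   [connectivityFeatures()].
#' @param k number of clusters.
#' @param nInit number of random restarts (default 500).
#' @param maxIter Lloyd iteration cap per restart.
#' @param seed RNG seed.
#' @return A [ClusterModel-class]; `@rowInfo` carries subject/window labels
#'   when available. The attribute `objectiveTrace` holds the per-iteration
#'   objective of the winning restart.
#' @export
kmeansL1 <- function(features, k, nInit = 500, maxIter = 100, seed = 1) {
  rowInfo <- NULL
  if (is.list(features) && !is.null(features$features)) {
    rowInfo <- features$rowInfo
    features <- features$features
  }
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < k) stop("fewer rows than clusters")
  set.seed(seed)
  best <- NULL
  for (i in seq_len(nInit)) {
    init <- features[sample.int(n, k), , drop = FALSE]
    fit <- kmeans_l1_cpp(features, init, maxIter)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(rowInfo))
    rowInfo <- data.frame(subject = "all", window = seq_len(n),
                          stringsAsFactors = FALSE)
  model <- new("ClusterModel", k = as.integer(k),
               centroids = best$centroids,
               assignment = as.integer(best$assignment) + 1L,
               rowInfo = rowInfo, objective = best$objective,
               nInit = as.integer(nInit), seed = as.integer(seed))
  attr(model, "objectiveTrace") <- best$objectiveTrace
  model
}

#' Relabel states by descending assignment count
#'
#' Makes state labels comparable across runs: state 1 becomes the most
#' frequent state, etc. Ties are broken by the original label order.
#'
#' @param model a [ClusterModel-class].
#' @param decreasing order states from most to least frequent (default).
#' @return The relabeled [ClusterModel-class].
#' @export
relabelBySize <- function(model, decreasing = TRUE) {
  counts <- tabulate(model@assignment, nbins = model@k)
  ord <- order(counts, decreasing = decreasing)
  map <- integer(model@k)
  map[ord] <- seq_len(model@k)
  initialize(model,
             centroids = model@centroids[ord, , drop = FALSE],
             assignment = map[model@assignment])
}

#' Cluster validity index (within / between distance ratio)
#'
#' Within-cluster distance is the mean L1 distance of rows to their own
#' centroid; between-cluster distance is the mean pairwise L1 distance among
#' centroids.
#'
#' @param features feature matrix (or [connectivityFeatures()] list).
#' @param model a [ClusterModel-class] with k >= 2.
#' @return the ratio (smaller is better).
#' @export
clusterValidity <- function(features, model) {
  if (is.list(features) && !is.null(features$features))
    features <- features$features
  stopifnot(is(model, "ClusterModel"))
  if (model@k < 2) stop("validity ratio needs k >= 2")
  D <- l1_distmat_cpp(as.matrix(features), model@centroids)
  within <- mean(D[cbind(seq_len(nrow(D)), model@assignment)])
  CC <- l1_distmat_cpp(model@centroids, model@centroids)
  between <- mean(CC[upper.tri(CC)])
  if (between <= 0) stop("identical centroids: between-cluster distance is zero")
  within / between
}

#' Elbow of a validity curve
#'
#' Returns the k whose point on the curve has the largest perpendicular
#' distance from the chord joining the curve's endpoints. A (numerically)
#' linear curve has no elbow: the smallest k is returned with
#' `noElbow = TRUE`.
#'
#' @param k increasing vector of cluster counts.
#' @param values validity index at each k.
#' @return list with `k` (selected), `distances`, `noElbow`.
#' @export
elbowPoint <- function(k, values) {
  stopifnot(length(k) == length(values), length(k) >= 2)
  x1 <- k[1]; y1 <- values[1]
  x2 <- k[length(k)]; y2 <- values[length(values)]
  nrm <- sqrt((y2 - y1)^2 + (x2 - x1)^2)
  d <- abs((y2 - y1) * k - (x2 - x1) * values + x2 * y1 - y2 * x1) / nrm
  scale <- max(abs(values)) + 1e-12
  if (max(d) < 1e-10 * max(1, scale))
    return(list(k = k[1], distances = d, noElbow = TRUE))
  list(k = k[which.max(d)], distances = d, noElbow = FALSE)
}

#' Select the number of states by the elbow criterion
#'
#' Clusters the features at each k in `kRange`, computes the validity index,
#' and picks the elbow of the validity curve.
#'
#' @param features feature matrix or [connectivityFeatures()] list.
#' @param kRange candidate cluster counts (default 2:8).
#' @param nInit restarts per k.
#' @param maxIter Lloyd iteration cap.
#' @param seed RNG seed.
#' @return list with `k` (selected), `validity` (curve), `models`,
#'   `noElbow`.
#' @export
selectK <- function(features, kRange = 2:8, nInit = 100, maxIter = 100,
                    seed = 1) {
  validity <- numeric(length(kRange))
  models <- vector("list", length(kRange))
  for (i in seq_along(kRange)) {
    models[[i]] <- kmeansL1(features, kRange[i], nInit = nInit,
                            maxIter = maxIter, seed = seed + i)
    validity[i] <- clusterValidity(features, models[[i]])
    if (!is.finite(validity[i]))
      stop(sprintf("non-finite validity index at k = %d", kRange[i]))
  }
  eb <- elbowPoint(kRange, validity)
  list(k = eb$k, kRange = kRange, validity = validity,
       models = models, noElbow = eb$noElbow)
}

#' Per-subject state dynamics metrics for one assignment sequence
#'
#' Given a sequence of window-state assignments: frequency is the proportion
#' of windows in each state; mean dwell time is the average length of the
#' maximal runs of each state (runs touching the sequence edges included);
#' the intertransition interval is the mean run length over all runs, i.e.
#' `W / (nTransitions + 1)`; the number of transitions is the number of runs
#' minus one.
#'
#' @param assignment integer sequence of states (length W >= 1).
#' @param nStates total number of states.
#' @return list with `frequency`, `meanDwell` (NA for unvisited states),
#'   `intertransitionInterval`, `nTransitions`.
#' @export
stateMetrics <- function(assignment, nStates) {
  stopifnot(length(assignment) >= 1)
  if (any(assignment < 1 | assignment > nStates))
    stop("unknown state index in assignment sequence")
  W <- length(assignment)
  runs <- rle(assignment)
  frequency <- tabulate(assignment, nbins = nStates) / W
  meanDwell <- vapply(seq_len(nStates), function(s) {
    len <- runs$lengths[runs$values == s]
    if (length(len)) mean(len) else NA_real_
  }, numeric(1))
  nRuns <- length(runs$lengths)
  list(frequency = frequency, meanDwell = meanDwell,
       intertransitionInterval = W / nRuns, nTransitions = nRuns - 1L)
}

#' State dynamics metrics for every subject in a clustering solution
#'
#' @param model a [ClusterModel-class] (or a named list of assignment
#'   vectors).
#' @param nStates number of states (taken from the model when omitted).
#' @return data.frame with one row per subject: `frequency.<s>`,
#'   `meanDwell.<s>`, `intertransitionInterval`, `nTransitions`.
#' @export
cohortStateMetrics <- function(model, nStates = NULL) {
  if (is(model, "ClusterModel")) {
    seqs <- split(model@assignment, model@rowInfo$subject)
    # preserve original subject order
    seqs <- seqs[unique(model@rowInfo$subject)]
    if (is.null(nStates)) nStates <- model@k
  } else {
    seqs <- model
    if (is.null(nStates)) nStates <- max(unlist(seqs))
  }
  rows <- lapply(names(seqs), function(id) {
    m <- stateMetrics(seqs[[id]], nStates)
    out <- data.frame(subject = id, stringsAsFactors = FALSE)
    for (s in seq_len(nStates)) {
      out[[paste0("frequency.", s)]] <- m$frequency[s]
      out[[paste0("meanDwell.", s)]] <- m$meanDwell[s]
    }
    out$intertransitionInterval <- m$intertransitionInterval
    out$nTransitions <- m$nTransitions
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

# greedy one-to-one matching of centroid rows by maximal correlation
matchCentroids <- function(A, B) {
  k <- nrow(A)
  C <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) for (j in seq_len(k))
    C[i, j] <- suppressWarnings(stats::cor(A[i, ], B[j, ]))
  C[!is.finite(C)] <- -1
  match <- integer(k)
  sims <- numeric(k)
  avail <- rep(TRUE, k)
  Cwork <- C
  for (step in seq_len(k)) {
    best <- which(Cwork == max(Cwork), arr.ind = TRUE)[1, ]
    match[best[1]] <- best[2]
    sims[best[1]] <- C[best[1], best[2]]
    Cwork[best[1], ] <- -Inf
    Cwork[, best[2]] <- -Inf
  }
  list(match = match, similarity = sims)
}

#' Split-half / bootstrap stability of connectivity states
#'
#' `split_half`: subjects are randomly split in two halves, each half is
#' clustered, and centroids are matched one-to-one across halves by greedy
#' maximal correlation; the matched correlations are the per-state
#' similarities. `bootstrap`: subjects are resampled with replacement,
#' clustered, and matched against the full-data centroids.
#'
#' @param features [connectivityFeatures()] list (subject labels are
#'   required) or a matrix plus `subjects`.
#' @param k number of states.
#' @param scheme `"split_half"` or `"bootstrap"`.
#' @param nReplicates number of resampling replicates.
#' @param nInit restarts per clustering fit.
#' @param seed RNG seed.
#' @param subjects subject label per row (when `features` is a matrix).
#' @return list of class `StabilityReport`: `scheme`, `similarity`
#'   (replicates x k matrix), `nReplicates`, `seed`, `skipped`.
#' @export
stabilityAnalysis <- function(features, k, scheme = c("split_half", "bootstrap"),
                              nReplicates = 100, nInit = 50, seed = 1,
                              subjects = NULL) {
  scheme <- match.arg(scheme)
  if (is.list(features) && !is.null(features$features)) {
    subjects <- features$rowInfo$subject
    features <- features$features
  }
  stopifnot(!is.null(subjects), nrow(features) >= 2 * k)
  ids <- unique(subjects)
  set.seed(seed)
  full <- NULL
  if (scheme == "bootstrap")
    full <- kmeansL1(features, k, nInit = nInit, seed = seed)
  sims <- matrix(NA_real_, nReplicates, k)
  skipped <- 0L
  for (r in seq_len(nReplicates)) {
    if (scheme == "split_half") {
      half <- sample(ids, floor(length(ids) / 2))
      ia <- subjects %in% half
      Xa <- features[ia, , drop = FALSE]
      Xb <- features[!ia, , drop = FALSE]
      if (nrow(unique(Xa)) < k || nrow(unique(Xb)) < k) {
        skipped <- skipped + 1L
        next
      }
      ma <- kmeansL1(Xa, k, nInit = nInit, seed = seed + 1000 + r)
      mb <- kmeansL1(Xb, k, nInit = nInit, seed = seed + 2000 + r)
      ref <- relabelBySize(ma)
      sims[r, ] <- matchCentroids(ref@centroids, mb@centroids)$similarity
    } else {
      boot <- sample(ids, length(ids), replace = TRUE)
      idx <- unlist(lapply(boot, function(b) which(subjects == b)))
      Xb <- features[idx, , drop = FALSE]
      if (nrow(unique(Xb)) < k) {
        skipped <- skipped + 1L
        next
      }
      mb <- kmeansL1(Xb, k, nInit = nInit, seed = seed + 3000 + r)
      sims[r, ] <- matchCentroids(relabelBySize(full)@centroids,
                                  mb@centroids)$similarity
    }
  }
  structure(list(scheme = scheme, similarity = sims,
                 nReplicates = nReplicates, seed = seed, skipped = skipped),
            class = "StabilityReport")
}
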