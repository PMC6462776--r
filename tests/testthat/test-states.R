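test_that("k = 1 centroid is the componentwise median (1-median optimality)", {
  set.seed(50)
  X <- matrix(rnorm(40), 10, 4)
  km <- kmeansL1(X, 1, nInit = 3, seed = 1)
  med <- apply(X, 2, median)
  expect_equal(as.vector(stateCentroids(km)), med, tolerance = 1e-12)
  expect_equal(km@objective, sum(abs(sweep(X, 2, med))))
})

test_that("well-separated blobs are recovered exactly", {
  blobs <- threeBlobFeatures()
  km <- kmeansL1(blobs$features, 3, nInit = 20, seed = 2)
  expect_equal(labelAccuracy(stateAssignment(km), blobs$labels, 3), 1)
})

test_that("k-means objective matches exhaustive 2-partition search at n = 6", {
  set.seed(51)
  X <- matrix(rnorm(12), 6, 2)
  km <- kmeansL1(X, 2, nInit = 100, seed = 3)
  expect_equal(km@objective, bruteForceL1TwoPartition(X), tolerance = 1e-10)
})

test_that("the objective is non-increasing within an initialization", {
  set.seed(52)
  X <- matrix(rnorm(400), 100, 4)
  km <- kmeansL1(X, 4, nInit = 5, seed = 4)
  tr <- attr(km, "objectiveTrace")
  expect_true(all(diff(tr) <= 1e-9))
  # every row is assigned to its nearest centroid
  D <- l1_distmat_cpp(X, stateCentroids(km))
  expect_equal(apply(D, 1, which.min), as.vector(stateAssignment(km)))
})

test_that("cluster validity follows hand computations and scaling", {
  # two singleton clusters at distance d, rows at distance a from centroids
  X <- rbind(c(0, 1), c(0, -1), c(10, 1), c(10, -1))
  model <- new("ClusterModel", k = 2L,
               centroids = rbind(c(0, 0), c(10, 0)),
               assignment = c(1L, 1L, 2L, 2L),
               rowInfo = data.frame(subject = "a", window = 1:4),
               objective = 4, nInit = 1L, seed = 1L)
  expect_equal(clusterValidity(X, model), 1 / 10)  # a = 1, d = 10
  # doubling the separation halves the ratio
  X2 <- X; X2[3:4, 1] <- 20
  model2 <- initialize(model, centroids = rbind(c(0, 0), c(20, 0)))
  expect_equal(clusterValidity(X2, model2), 0.5 * clusterValidity(X, model))
  # rows on their centroids give zero
  X0 <- rbind(c(0, 0), c(10, 0))
  model0 <- initialize(model, assignment = c(1L, 2L),
                       rowInfo = data.frame(subject = "a", window = 1:2))
  expect_equal(clusterValidity(X0, model0), 0)
  ident <- initialize(model, centroids = rbind(c(0, 0), c(0, 0)))
  expect_error(clusterValidity(X, ident), "identical centroids")
})

test_that("elbow detection finds kinks and flags linear curves", {
  # piecewise-linear curve with a sharp kink at k = 4
  k <- 2:8
  v <- ifelse(k <= 4, 10 - 2 * (k - 2), 6 - 0.1 * (k - 4))
  expect_equal(elbowPoint(k, v)$k, 4)
  lin <- elbowPoint(k, 10 - k)
  expect_true(lin$noElbow)
  expect_equal(lin$k, 2)
})

test_that("selectK recovers k = 3 on separable blob data", {
  blobs <- threeBlobFeatures(nPerBlob = 40)
  sel <- selectK(blobs$features, kRange = 2:6, nInit = 10, seed = 5)
  expect_equal(sel$k, 3)
  expect_false(sel$noElbow)
})

test_that("state metrics match hand-enumerated runs", {
  m <- stateMetrics(rep(2L, 107), nStates = 3)
  expect_equal(m$frequency, c(0, 1, 0))
  expect_equal(m$meanDwell[2], 107)
  expect_equal(m$nTransitions, 0L)
  expect_equal(m$intertransitionInterval, 107)

  m2 <- stateMetrics(c(1, 1, 2, 2, 2, 1), nStates = 2)
  expect_equal(m2$frequency, c(0.5, 0.5))
  expect_equal(m2$meanDwell, c(1.5, 3))
  expect_equal(m2$nTransitions, 2L)
  expect_equal(m2$intertransitionInterval, 2)

  alt <- stateMetrics(rep(c(1L, 2L), 5), nStates = 2)
  expect_equal(alt$nTransitions, 9L)
  expect_equal(alt$meanDwell, c(1, 1))

  expect_error(stateMetrics(c(1, 4), nStates = 3), "unknown state")
})

test_that("run-length bookkeeping identities hold on random sequences", {
  set.seed(53)
  for (r in 1:20) {
    W <- sample(5:200, 1)
    k <- sample(2:5, 1)
    s <- sample.int(k, W, replace = TRUE)
    m <- stateMetrics(s, k)
    expect_equal(sum(m$frequency), 1)
    runs <- rle(s)
    expect_equal(m$nTransitions, length(runs$lengths) - 1L)
    expect_lte(m$nTransitions, W - 1)
    expect_equal(m$intertransitionInterval, W / (m$nTransitions + 1))
    # total run length over states equals W
    visited <- which(!is.na(m$meanDwell))
    nRunsPerState <- table(factor(runs$values, levels = 1:k))
    expect_equal(sum(m$meanDwell[visited] * nRunsPerState[visited]), W)
  }
})

test_that("cohort metrics keep one row per subject and coherent frequencies", {
  blobs <- threeBlobFeatures()
  km <- kmeansL1(list(features = blobs$features, rowInfo = blobs$rowInfo),
                 3, nInit = 10, seed = 6)
  cm <- cohortStateMetrics(km)
  expect_equal(nrow(cm), length(unique(blobs$rowInfo$subject)))
  freq <- as.matrix(cm[, grep("^frequency", names(cm))])
  expect_equal(unname(rowSums(freq)), rep(1, nrow(cm)))
})

test_that("relabeling by size orders states by assignment count", {
  blobs <- threeBlobFeatures(nPerBlob = 30)
  idx <- c(1:30, 31:50, 61:70)  # unbalanced blob sizes 30/20/10
  km <- relabelBySize(kmeansL1(blobs$features[idx, ], 3, nInit = 10, seed = 7))
  counts <- tabulate(stateAssignment(km), 3)
  expect_true(all(diff(counts) <= 0))
})

test_that("duplicated halves give perfect split-half similarity", {
  set.seed(54)
  X <- threeBlobFeatures(nPerBlob = 20, subjectsPerBlob = 2)
  # duplicate the data under new subject ids: both halves identical
  feats <- rbind(X$features, X$features)
  subj <- c(X$rowInfo$subject, paste0(X$rowInfo$subject, "_dup"))
  # force a split that puts originals in one half via many replicates:
  rep <- stabilityAnalysis(feats, 3, "split_half", nReplicates = 10,
                           nInit = 10, seed = 8, subjects = subj)
  expect_gt(median(rep$similarity, na.rm = TRUE), 0.95)
})

test_that("bootstrap stability separates separable from unseparable data", {
  blobs <- threeBlobFeatures(nPerBlob = 30)
  sep <- stabilityAnalysis(list(features = blobs$features,
                                rowInfo = blobs$rowInfo),
                           3, "bootstrap", nReplicates = 20, nInit = 10,
                           seed = 9)
  set.seed(55)
  noise <- list(features = matrix(rnorm(90 * 20), 90, 20),
                rowInfo = blobs$rowInfo)
  uns <- stabilityAnalysis(noise, 3, "bootstrap", nReplicates = 20,
                           nInit = 10, seed = 10)
  msep <- apply(sep$similarity, 2, median, na.rm = TRUE)
  muns <- apply(uns$similarity, 2, median, na.rm = TRUE)
  expect_gt(min(msep), 0.95)
  expect_gt(median(msep) - median(muns), 0.2)
})
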