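makeWC <- function(arr, stage = "z", id = "s1") {
  new("WindowedConnectivity", matrices = arr,
      windowStarts = seq_len(dim(arr)[3]), stage = stage,
      lambda = NA_real_, subjectId = id,
      networkNames = paste0("N", seq_len(dim(arr)[1])))
}

test_that("taper weights are symmetric, normalized, and limit to uniform", {
  tp <- makeTaper()
  expect_length(tp$weights, 22)
  expect_equal(sum(tp$weights), 1)
  expect_lt(max(abs(tp$weights - rev(tp$weights))), 1e-12)
  # interior heavier than edges
  expect_gt(tp$weights[11], tp$weights[1])
  for (w in c(5, 18, 28)) for (s in c(0.5, 3, 7)) {
    t2 <- makeTaper(w, s)
    expect_equal(sum(t2$weights), 1)
    expect_lt(max(abs(t2$weights - rev(t2$weights))), 1e-12)
  }
  tiny <- makeTaper(22, 1e-6)
  expect_lt(max(abs(tiny$weights - 1 / 22)), 1e-6)
  expect_error(makeTaper(1), "width")
})

test_that("window counts follow floor((T-w)/step)+1", {
  expect_equal(windowCount(128, 22, 1), 107L)
  expect_equal(windowCount(22, 22, 1), 1L)
  expect_equal(windowCount(128, 18, 1), 111L)
  expect_error(windowCount(10, 22), "short")
})

test_that("uniform-taper windowed covariance matches the plain estimator", {
  set.seed(10)
  X <- matrix(rnorm(40 * 4), 40, 4)
  tc <- timecourseSet(X, TR = 3)
  w <- 10
  wc <- windowedCovariance(tc, makeTaper(w, 1e-6))
  expect_equal(nWindows(wc), 31L)
  for (i in c(1, 15, 31)) {
    seg <- X[i:(i + w - 1), ]
    oracle <- cov(seg) * (w - 1) / w  # weights 1/w -> population normalization
    expect_lt(max(abs(wc@matrices[, , i] - oracle)), 1e-10)
  }
  # constant signal: all-zero covariance
  cc <- windowedCovariance(timecourseSet(matrix(1, 30, 3), TR = 3),
                           makeTaper(10, 2))
  expect_equal(max(abs(cc@matrices)), 0)
  # full-scale window count
  tc128 <- timecourseSet(matrix(rnorm(128 * 3), 128, 3), TR = 3)
  expect_equal(nWindows(windowedCovariance(tc128, makeTaper())), 107L)
})

test_that("graphical LASSO handles the analytic special cases", {
  # diagonal S, lambda 0: precision is the elementwise inverse
  fit <- graphicalLasso(diag(c(2, 5, 0.5)), 0)
  expect_equal(fit$precision, diag(c(0.5, 0.2, 2)), tolerance = 1e-8)
  # lambda >= max |offdiag|: fully sparse precision
  S <- randomSPD(4, seed = 2)
  lmax <- max(abs(S[upper.tri(S)]))
  fit <- graphicalLasso(S, lmax + 1e-6)
  off <- fit$precision
  diag(off) <- 0
  expect_lt(max(abs(off)), 1e-8)
  expect_equal(diag(fit$covariance), diag(S), tolerance = 1e-8)
})

test_that("graphical LASSO matches an independent proximal-gradient oracle", {
  S <- randomSPD(3, seed = 5)
  lambda <- 0.1
  fit <- graphicalLasso(S, lambda, tol = 1e-9)
  oracle <- glassoProxGrad(S, lambda, steps = 20000, eta = 5e-3)
  expect_lt(abs(glassoObjective(fit$precision, S, lambda) - oracle$objective),
            1e-6)
})

test_that("lambda -> 0 recovers the sample covariance; precision stays SPD", {
  S <- randomSPD(5, seed = 6)
  fit <- graphicalLasso(S, 1e-8)
  expect_lt(max(abs(fit$covariance - S)), 1e-4)
  for (l in c(0.01, 0.1, 0.5)) {
    f <- graphicalLasso(S, l)
    ev <- eigen(f$precision, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
    expect_lt(max(abs(f$precision - t(f$precision))), 1e-10)
  }
})

test_that("cross-validated penalty selection follows its contracts", {
  set.seed(20)
  X <- matrix(rnorm(60 * 3), 60, 3)
  tc <- timecourseSet(X, TR = 3)
  wc <- windowedCovariance(tc, makeTaper(10, 2))
  # a single-point grid returns that penalty
  sel <- selectLambda(wc, grid = 0.2, nFolds = 5)
  expect_equal(sel$lambda, 0.2)
  # too few windows for the folds
  short <- windowedCovariance(timecourseSet(matrix(rnorm(36), 12, 3), TR = 3),
                              makeTaper(10, 2))
  expect_error(selectLambda(short, nFolds = 20), "smaller nFolds")
})

test_that("held-out scores equal a hand-coded bivariate Gaussian density oracle", {
  set.seed(21)
  X <- matrix(rnorm(40 * 2), 40, 2)
  wc <- windowedCovariance(timecourseSet(X, TR = 3), makeTaper(8, 2))
  lambda <- 0.05
  nFolds <- 4
  sel <- selectLambda(wc, grid = lambda, nFolds = nFolds)
  W <- nWindows(wc)
  foldId <- as.integer(cut(seq_len(W), nFolds, labels = FALSE))
  for (f in seq_len(nFolds)) {
    Strain <- apply(wc@matrices[, , foldId != f, drop = FALSE], c(1, 2), mean)
    Th <- graphicalLasso(Strain, lambda)$precision
    # bivariate closed forms: det and trace written out entrywise
    detTh <- Th[1, 1] * Th[2, 2] - Th[1, 2]^2
    ll <- sapply(which(foldId == f), function(i) {
      St <- wc@matrices[, , i]
      tr <- St[1, 1] * Th[1, 1] + St[2, 2] * Th[2, 2] + 2 * St[1, 2] * Th[1, 2]
      0.5 * (log(detTh) - tr - 2 * log(2 * pi))
    })
    expect_lt(abs(sel$scores[f, 1] - mean(ll)), 1e-8)
  }
})

test_that("CV curve has an interior maximum for sparse-precision data", {
  # data generated from a sparse precision matrix; the held-out likelihood
  # should peak strictly inside a wide penalty grid in most replicates
  grid <- lambdaGrid(8, 1e-3, 1.5)
  p <- 8
  interior <- 0
  nRep <- 10
  for (r in seq_len(nRep)) {
    set.seed(100 + r)
    Theta <- diag(p)
    nz <- cbind(1:4, 5:8)
    Theta[nz] <- Theta[nz[, 2:1]] <- 0.4
    Sigma <- solve(Theta)
    X <- matrix(rnorm(80 * p), 80, p) %*% chol(Sigma)
    wc <- windowedCovariance(timecourseSet(X, TR = 3), makeTaper(12, 3))
    sel <- selectLambda(wc, grid = grid, nFolds = 5)
    pos <- which.max(sel$meanScores)
    if (pos > 1 && pos < length(grid)) interior <- interior + 1
  }
  expect_gte(interior, 0.9 * nRep)
})

test_that("Fisher z transform matches closed forms and is odd", {
  C <- array(0, c(2, 2, 1))
  C[, , 1] <- matrix(c(4, 2 * 0.5 * 3, 2 * 0.5 * 3, 9), 2)  # r = 0.5
  z <- toFisherZ(makeWC(C, stage = "covariance"))
  expect_equal(z@matrices[1, 2, 1], atanh(0.5))
  expect_equal(z@matrices[1, 1, 1], 0)
  for (r in seq(-0.9, 0.9, by = 0.3)) {
    Cr <- array(c(1, r, r, 1), c(2, 2, 1))
    Cm <- array(c(1, -r, -r, 1), c(2, 2, 1))
    zp <- toFisherZ(makeWC(Cr, "covariance"))@matrices[1, 2, 1]
    zm <- toFisherZ(makeWC(Cm, "covariance"))@matrices[1, 2, 1]
    expect_equal(zp, -zm)
    expect_equal(zp, atanh(r))
  }
  perf <- array(c(1, 1, 1, 1), c(2, 2, 1))
  expect_error(toFisherZ(makeWC(perf, "covariance")), "Fisher z undefined")
})

test_that("residualization removes covariate effects and is idempotent", {
  set.seed(30)
  n <- 12; N <- 3; W <- 4
  age <- seq(60, 82, length.out = n)
  cov <- data.frame(subject_id = paste0("s", 1:n), age = age,
                    gender = rep(c("M", "F"), 6),
                    study = rep(c("study1", "study2"), each = 6))
  base <- array(rnorm(N * N * W), c(N, N, W))
  zl <- lapply(1:n, function(i) {
    a <- array(0, c(N, N, W))
    for (w in 1:W) {
      m <- matrix(0, N, N)
      m[upper.tri(m)] <- 0.1 * base[, , w][upper.tri(base[, , w])] +
        0.03 * (age[i] - mean(age))
      a[, , w] <- m + t(m)
    }
    makeWC(a, "z", paste0("s", i))
  })
  names(zl) <- cov$subject_id
  out <- residualizeConnectivity(zl, cov, columns = "age")
  # z was an exact linear function of age: across subjects variance vanishes
  v <- sapply(1:W, function(w) var(sapply(out, function(o) o@matrices[1, 2, w])))
  v0 <- sapply(1:W, function(w) var(sapply(zl, function(o) o@matrices[1, 2, w])))
  expect_lt(max(v / v0), 1e-10)
  # grand level retained
  expect_equal(mean(sapply(out, function(o) o@matrices[1, 2, 1])),
               mean(sapply(zl, function(o) o@matrices[1, 2, 1])))
  # idempotence
  out2 <- residualizeConnectivity(out, cov, columns = "age")
  expect_lt(max(abs(out2[[3]]@matrices - out[[3]]@matrices)), 1e-10)
  # an orthogonal covariate leaves the data unchanged
  cov$ortho <- rep(c(-1, 1), 6)[sample(12)]
  zConst <- lapply(zl, function(z) z)
  outO <- residualizeConnectivity(zl, cov, columns = "gender")
  gnum <- as.numeric(factor(cov$gender)) - 1
  y <- sapply(zl, function(o) o@matrices[1, 2, 1])
  if (abs(cor(gnum, y)) < 1e-12)
    expect_lt(max(abs(outO[[1]]@matrices - zl[[1]]@matrices)), 1e-10)
  # collinear design errors
  cov$age2 <- cov$age * 2
  expect_error(residualizeConnectivity(zl, cov, columns = c("age", "age2")),
               "collinear")
})

test_that("connectivity variability follows the closed forms", {
  N <- 4
  m <- matrix(rnorm(N * N), N, N)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  same <- array(rep(m, 3), c(N, N, 3))
  v <- connectivityVariability(makeWC(same))
  expect_equal(max(v$sdMatrix), 0)
  expect_equal(v$overallMean, 0)
  # two windows, z and -z: SD = |z| * sqrt(2)
  two <- array(c(m, -m), c(N, N, 2))
  v2 <- connectivityVariability(makeWC(two))
  expect_equal(v2$sdMatrix, abs(m) * sqrt(2), ignore_attr = TRUE)
  expect_equal(v2$overallMean, sqrt(2) * mean(abs(m[upper.tri(m)])))
  expect_equal(v2$networkMeans, rowSums(abs(m) * sqrt(2)) / (N - 1),
               ignore_attr = TRUE)
  expect_error(connectivityVariability(makeWC(array(m, c(N, N, 1)))),
               "at least 2 windows")
})

test_that("SD matrices are robust to the window width", {
  co <- tinyCohort(nPerGroup = 3, T = 60)
  cleaned <- lapply(co$timecourses, function(tc) postprocess(tc)$timecourse)
  sds <- lapply(c(18, 22, 28), function(w) {
    zl <- lapply(cleaned, function(tc) {
      subjectConnectivity(tc, makeTaper(w, 3), lambda = 0.1)$z
    })
    res <- residualizeConnectivity(zl, co$manifest)
    rowMeans(sapply(res, function(r) {
      sdm <- connectivityVariability(r)$sdMatrix
      sdm[upper.tri(sdm)]
    }))
  })
  expect_gt(cor(sds[[1]], sds[[2]]), 0.8)
  expect_gt(cor(sds[[2]], sds[[3]]), 0.8)
})
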