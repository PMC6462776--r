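# Independent oracles and small fixture builders used across the test files.

# Floyd-Warshall all-pairs shortest paths (dense triple loop)
floydWarshall <- function(adj) {
  N <- nrow(adj)
  D <- matrix(Inf, N, N)
  diag(D) <- 0
  D[adj != 0] <- 1
  for (k in seq_len(N)) for (i in seq_len(N)) for (j in seq_len(N))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

efficiencyFromDistances <- function(D) {
  N <- nrow(D)
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv) / (N * (N - 1))
}

# graphical-LASSO objective: log det(Theta) - tr(S Theta) - lambda ||offdiag||_1
glassoObjective <- function(Theta, S, lambda) {
  ev <- eigen(Theta, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) return(-Inf)
  sum(log(ev)) - sum(S * Theta) - lambda * (sum(abs(Theta)) - sum(abs(diag(Theta))))
}

# proximal-gradient (ISTA) maximizer of the graphical-LASSO objective,
# independent of the block-coordinate-descent implementation under test
glassoProxGrad <- function(S, lambda, steps = 200000, eta = 1e-3) {
  p <- nrow(S)
  Theta <- diag(1 / diag(S))
  soft <- function(M, t) {
    out <- sign(M) * pmax(abs(M) - t, 0)
    diag(out) <- diag(M)  # diagonal unpenalized
    out
  }
  best <- Theta
  bestObj <- glassoObjective(Theta, S, lambda)
  for (i in seq_len(steps)) {
    G <- solve(Theta) - S
    Thn <- soft(Theta + eta * G, eta * lambda)
    Thn <- (Thn + t(Thn)) / 2
    ev <- min(eigen(Thn, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 0) { eta <- eta / 2; next }
    Theta <- Thn
    obj <- glassoObjective(Theta, S, lambda)
    if (obj > bestObj) { bestObj <- obj; best <- Theta }
  }
  list(theta = best, objective = bestObj)
}

randomSPD <- function(p, seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(p * (p + 2)), p + 2, p)
  crossprod(A) / (p + 2)
}

# brute-force minimum L1 k-means objective over all 2-partitions
bruteForceL1TwoPartition <- function(X) {
  n <- nrow(X)
  best <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {
    g1 <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    g2 <- setdiff(seq_len(n), g1)
    if (!length(g1) || !length(g2)) next
    obj <- 0
    for (g in list(g1, g2)) {
      med <- apply(X[g, , drop = FALSE], 2, median)
      obj <- obj + sum(abs(sweep(X[g, , drop = FALSE], 2, med)))
    }
    if (obj < best) best <- obj
  }
  best
}

# rank-sum Kruskal-Wallis H by direct formula (tie-corrected)
kruskalOracle <- function(groups) {
  x <- unlist(groups)
  n <- length(x)
  rk <- rank(x)
  idx <- rep(seq_along(groups), lengths(groups))
  H <- 12 / (n * (n + 1)) *
    sum(tapply(rk, idx, sum)^2 / lengths(groups)) - 3 * (n + 1)
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (n^3 - n))
}

spearmanOracle <- function(x, y) {
  cor(rank(x), rank(y))
}

# tiny well-separated three-blob feature set with subject labels
threeBlobFeatures <- function(nPerBlob = 30, p = 4, sep = 10, seed = 42,
                              subjectsPerBlob = 3) {
  set.seed(seed)
  # distinct non-degenerate center patterns (centroid correlations need
  # non-constant vectors, as real connectivity centroids are)
  centers <- sep * outer(1:3, seq_len(p), function(b, j) sin(b * j))
  X <- do.call(rbind, lapply(1:3, function(b) {
    sweep(matrix(rnorm(nPerBlob * p, sd = 1), nPerBlob, p), 2, centers[b, ], "+")
  }))
  labels <- rep(1:3, each = nPerBlob)
  subjects <- paste0("s", rep(seq_len(3 * subjectsPerBlob),
                              each = nPerBlob / subjectsPerBlob))
  list(features = X, labels = labels,
       rowInfo = data.frame(subject = subjects,
                            window = sequence(rep(nPerBlob / subjectsPerBlob,
                                                  3 * subjectsPerBlob))))
}

# small clean cohort of timecourse objects for io/pipeline tests
tinyCohort <- function(nPerGroup = 3, T = 60, seed = 7, nNetworks = 6,
                       switchRate = 0.1) {
  model <- generateStateModel(nStates = 2, nNetworks = nNetworks,
                              strength = 0.7, nModules = 2)
  cohortSpec(
    groups = list(
      A = list(n = nPerGroup, markov = stationaryMarkov(c(0.5, 0.5), switchRate)),
      B = list(n = nPerGroup, markov = stationaryMarkov(c(0.3, 0.7), switchRate))
    ),
    T = T, noiseSd = 0.1, trendRange = c(-0.2, 0.2),
    spikeRate = 0, spikeAmplitude = 0, seed = seed
  ) |> simulateCohort(model = model)
}
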