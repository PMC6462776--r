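#' Build a latent connectivity-state model with block structure
#'
#' Constructs `nStates` correlation-scale covariance matrices with signed
#' block (module) structure. The first state is the "strong" state: large
#' positive within- and between-module correlations plus negative blocks
#' against a third module. The second state is the "sparse" state with much
#' weaker off-diagonal structure; further states repeat the strong pattern
#' on rotated module pairs. Each raw pattern matrix is shrunk toward the
#' identity just enough to guarantee a minimum eigenvalue of `minEigen`,
#' which keeps every state symmetric positive definite with unit diagonal.
#'
#' @param nStates number of latent states (>= 1).
#' @param nNetworks number of networks N (>= 2).
#' @param strength magnitude of the strongest off-diagonal block (before
#'   shrinkage); 0 gives identity matrices.
#' @param nModules number of contiguous network modules.
#' @param minEigen minimum eigenvalue enforced by shrinkage toward identity.
#' @param jitterSd sd of symmetric Gaussian jitter added to the off-diagonal
#'   pattern (0 = deterministic patterns).
#' @param sparseState index of the sparse state (default 2); `NA` makes all
#'   states strong rotated-module patterns (useful for scenarios that need
#'   roughly equidistant states).
#' @param seed RNG seed used when `jitterSd > 0`.
#' @return A [StateModel-class] with states ordered strong first, sparse second.
#' @export
generateStateModel <- function(nStates = 3, nNetworks = 27, strength = 0.6,
                               nModules = 4, minEigen = 0.1, jitterSd = 0,
                               sparseState = 2, seed = NULL) {
  stopifnot(nStates >= 1, nNetworks >= 2, strength >= 0,
            minEigen > 0, minEigen < 1)
  if (!is.null(seed)) set.seed(seed)
  nModules <- min(nModules, nNetworks)
  module <- sort(rep_len(seq_len(nModules), nNetworks))
  same <- outer(module, module, "==")
  blockPair <- function(a, b) {
    outer(module, module, function(x, y) (x == a & y == b) | (x == b & y == a))
  }
  # module-pair rotations for the strong patterns, ordered so consecutive
  # patterns share as few modules as possible
  pairSeq <- if (nModules >= 2) {
    cmb <- utils::combn(nModules, 2)
    picked <- 1L
    remaining <- setdiff(seq_len(ncol(cmb)), 1L)
    while (length(remaining)) {
      prev <- cmb[, picked[length(picked)]]
      overlap <- vapply(remaining,
                        function(j) length(intersect(cmb[, j], prev)), 0L)
      nxt <- remaining[which.min(overlap)]
      picked <- c(picked, nxt)
      remaining <- setdiff(remaining, nxt)
    }
    cmb[, picked, drop = FALSE]
  } else matrix(c(1, 1), 2)

  strongPattern <- function(M, r) {
    ab <- pairSeq[, 1 + (r - 1) %% ncol(pairSeq)]
    a <- ab[1]; b <- ab[2]
    other <- setdiff(seq_len(nModules), c(a, b))[1]
    M[same] <- 0.15 * strength
    M[blockPair(a, a)] <- M[blockPair(b, b)] <- strength
    if (a != b) M[blockPair(a, b)] <- 0.7 * strength
    if (!is.na(other))
      M[blockPair(a, other)] <- M[blockPair(b, other)] <- -0.5 * strength
    M
  }

  covs <- vector("list", nStates)
  rot <- 0
  for (s in seq_len(nStates)) {
    M <- diag(nNetworks)
    if (!is.na(sparseState) && s == sparseState) {
      # sparse state: weak within-module structure only
      M[same] <- 0.2 * strength
      if (nModules >= 4) M[blockPair(3, 4)] <- 0.1 * strength
    } else {
      # strong states occupy rotated module pairs, so every non-sparse
      # state has its own connection topology and a comparable
      # within-state spread (a rescaled copy of another state would not
      # be separable from it)
      rot <- rot + 1
      M <- strongPattern(M, rot)
    }
    diag(M) <- 1
    if (jitterSd > 0) {
      J <- matrix(stats::rnorm(nNetworks^2, sd = jitterSd), nNetworks)
      J <- (J + t(J)) / 2
      diag(J) <- 0
      M <- M + J
    }
    B <- M - diag(nNetworks)
    lmin <- min(eigen(B, symmetric = TRUE, only.values = TRUE)$values)
    # eigmin(I + cB) = 1 + c*eigmin(B); shrink so it is >= minEigen
    cshrink <- if (lmin >= 0) 1 else min(1, (1 - minEigen) / (-lmin))
    C <- diag(nNetworks) + cshrink * B
    ev <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 0)
      stop(sprintf("state %d: constructed covariance is not positive definite", s))
    covs[[s]] <- C
  }
  labels <- paste0("strong", cumsum(seq_len(nStates) != sparseState |
                                      is.na(sparseState)))
  if (!is.na(sparseState) && sparseState <= nStates) labels[sparseState] <- "sparse"
  if (labels[1] == "strong1" && !"strong2" %in% labels) labels[1] <- "strong"
  stateModel(covs, labels[seq_len(nStates)])
}

#' Markov chain with a prescribed stationary distribution
#'
#' Builds the transition matrix `(1 - a) I + a 1 pi'`: with probability
#' `1 - switchRate` the chain stays put, otherwise it redraws the state from
#' `pi`. The stationary distribution is exactly `pi` and the mean dwell time
#' in state i is `1 / (switchRate * (1 - pi_i))` steps.
#'
#' @param pi target stationary distribution.
#' @param switchRate redraw probability per step, in (0, 1].
#' @return A [MarkovSpec-class].
#' @export
stationaryMarkov <- function(pi, switchRate = 0.25) {
  stopifnot(switchRate > 0, switchRate <= 1, all(pi >= 0), sum(pi) > 0)
  pi <- pi / sum(pi)
  k <- length(pi)
  P <- (1 - switchRate) * diag(k) + switchRate * matrix(pi, k, k, byrow = TRUE)
  markovSpec(pi, P)
}

#' Simulate a latent state sequence
#' @param markov a [MarkovSpec-class].
#' @param T sequence length.
#' @return integer vector of states in `1..k`.
#' @export
simulateMarkovChain <- function(markov, T) {
  stopifnot(is(markov, "MarkovSpec"), T >= 1)
  k <- length(markov@initialProbs)
  s <- integer(T)
  s[1] <- sample.int(k, 1, prob = markov@initialProbs)
  P <- markov@transitionMatrix
  for (t in seq_len(T - 1)) s[t + 1] <- sample.int(k, 1, prob = P[s[t], ])
  s
}

#' Simulate one subject's time courses from a switching-state model
#'
#' Emission model: at each time point the observation is zero-mean
#' multivariate Gaussian with the active state's covariance; states switch
#' instantaneously at the sampling resolution. Optional polynomial trends
#' (orders 1-3), additive spikes on random (time, network) cells, and white
#' noise exercise the postprocessing stage.
#'
#' @param model a [StateModel-class].
#' @param markov a [MarkovSpec-class] over the same number of states.
#' @param T number of time points (>= 2).
#' @param TR sampling interval in seconds.
#' @param noiseSd sd of additive white Gaussian noise.
#' @param trendRange length-2 range for per-network polynomial trend
#'   coefficients (orders 1-3 on time scaled to \[-1, 1\]); NULL for no trend.
#' @param spikeRate per-cell probability of an additive spike.
#' @param spikeAmplitude absolute spike amplitude (sign randomized).
#' @param subjectId subject identifier.
#' @param seed optional RNG seed.
#' @return list with `timecourse` ([TimecourseSet-class]), `states` (latent
#'   sequence) and `spikes` (data.frame of injected positions).
#' @export
simulateSubject <- function(model, markov, T = 128, TR = 3, noiseSd = 0,
                            trendRange = NULL, spikeRate = 0,
                            spikeAmplitude = 0, subjectId = "subject",
                            seed = NULL) {
  stopifnot(is(model, "StateModel"), is(markov, "MarkovSpec"), T >= 2)
  k <- length(model@covariances)
  if (length(markov@initialProbs) != k)
    stop(sprintf("state model has %d states but Markov spec has %d",
                 k, length(markov@initialProbs)))
  if (!is.null(seed)) set.seed(seed)
  N <- nrow(model@covariances[[1]])
  states <- simulateMarkovChain(markov, T)
  chols <- lapply(model@covariances, chol)
  Z <- matrix(stats::rnorm(T * N), T, N)
  X <- matrix(0, T, N)
  for (s in seq_len(k)) {
    idx <- which(states == s)
    if (length(idx)) X[idx, ] <- Z[idx, , drop = FALSE] %*% chols[[s]]
  }
  if (!is.null(trendRange)) {
    tt <- seq(-1, 1, length.out = T)
    basis <- cbind(tt, tt^2, tt^3)
    coef <- matrix(stats::runif(3 * N, trendRange[1], trendRange[2]), 3, N)
    X <- X + basis %*% coef
  }
  spikes <- data.frame(time = integer(0), network = integer(0),
                       amplitude = numeric(0))
  if (spikeRate > 0 && spikeAmplitude != 0) {
    hit <- which(matrix(stats::runif(T * N) < spikeRate, T, N), arr.ind = TRUE)
    if (nrow(hit)) {
      amp <- spikeAmplitude * sample(c(-1, 1), nrow(hit), replace = TRUE)
      X[hit] <- X[hit] + amp
      spikes <- data.frame(time = hit[, 1], network = hit[, 2], amplitude = amp)
    }
  }
  if (noiseSd > 0) X <- X + matrix(stats::rnorm(T * N, sd = noiseSd), T, N)
  list(
    timecourse = timecourseSet(X, TR, subjectId = subjectId),
    states = states,
    spikes = spikes
  )
}

#' Specify a synthetic cohort
#'
#' @param groups named list; each element a list with `n` (subjects) and
#'   `markov` (a [MarkovSpec-class]) for that group.
#' @param T time points per subject.
#' @param TR sampling interval in seconds.
#' @param noiseSd,trendRange,spikeRate,spikeAmplitude passed to
#'   [simulateSubject()].
#' @param ageMean,ageSd age distribution (years).
#' @param femaleProb probability a subject is female.
#' @param study2Prob probability of membership in the second study.
#' @param seed RNG seed for the whole cohort.
#' @return list of class `CohortSpec`.
#' @export
cohortSpec <- function(groups, T = 128, TR = 3, noiseSd = 0.2,
                       trendRange = c(-0.4, 0.4), spikeRate = 0.003,
                       spikeAmplitude = 5, ageMean = 76, ageSd = 7.5,
                       femaleProb = 0.33, study2Prob = 0.56, seed = 1) {
  if (length(groups) == 0) stop("groups must be a nonempty list")
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("groups must be named")
  for (g in names(groups)) {
    if (is.null(groups[[g]]$n) || groups[[g]]$n < 0)
      stop(sprintf("group '%s': n must be >= 0", g))
    if (!is(groups[[g]]$markov, "MarkovSpec"))
      stop(sprintf("group '%s': markov must be a MarkovSpec", g))
  }
  stopifnot(T >= 2, TR > 0)
  structure(list(groups = groups, T = T, TR = TR, noiseSd = noiseSd,
                 trendRange = trendRange, spikeRate = spikeRate,
                 spikeAmplitude = spikeAmplitude, ageMean = ageMean,
                 ageSd = ageSd, femaleProb = femaleProb,
                 study2Prob = study2Prob, seed = as.integer(seed)),
            class = "CohortSpec")
}

#' Default three-group cohort specification
#'
#' Emulates the structure of the study cohort: 31 controls, 29 AD and 31 DLB
#' subjects, 128 time points at TR = 3 s, three latent states. Group effects
#' are encoded only through state occupancy: controls visit the three states
#' in a relatively balanced way, while the patient groups occupy the strongly
#' connected state less and the sparse state more (most strongly in DLB),
#' with the sparse state the most common overall.
#'
#' @param seed RNG seed.
#' @param switchRate Markov redraw probability per TR.
#' @return A `CohortSpec`.
#' @export
defaultCohortSpec <- function(seed = 1, switchRate = 0.25) {
  cohortSpec(
    groups = list(
      HC  = list(n = 31, markov = stationaryMarkov(c(0.34, 0.40, 0.26), switchRate)),
      AD  = list(n = 29, markov = stationaryMarkov(c(0.20, 0.52, 0.28), switchRate)),
      DLB = list(n = 31, markov = stationaryMarkov(c(0.14, 0.60, 0.26), switchRate))
    ),
    seed = seed
  )
}

#' Simulate a synthetic cohort with ground truth
#'
#' Deterministic given `spec$seed`. Subject covariates (age, gender, study)
#' are drawn from the distributions declared in the cohort specification.
#'
#' @param spec a `CohortSpec` from [cohortSpec()].
#' @param model optional [StateModel-class]; by default a 3-state, 27-network
#'   block model from [generateStateModel()].
#' @return list with `timecourses` (named list of [TimecourseSet-class]),
#'   `manifest` (data.frame: subject_id, group, age, gender, study, seed),
#'   `truth` (per-subject latent states and spike positions), `model`, `spec`.
#' @export
simulateCohort <- function(spec, model = NULL) {
  stopifnot(inherits(spec, "CohortSpec"))
  nStates <- length(spec$groups[[1]]$markov@initialProbs)
  if (is.null(model)) model <- generateStateModel(nStates = nStates)
  set.seed(spec$seed)
  timecourses <- list()
  truth <- list()
  rows <- list()
  for (g in names(spec$groups)) {
    grp <- spec$groups[[g]]
    if (grp$n == 0) next
    for (i in seq_len(grp$n)) {
      id <- sprintf("%s%02d", g, i)
      sim <- simulateSubject(model, grp$markov, T = spec$T, TR = spec$TR,
                             noiseSd = spec$noiseSd,
                             trendRange = spec$trendRange,
                             spikeRate = spec$spikeRate,
                             spikeAmplitude = spec$spikeAmplitude,
                             subjectId = id)
      timecourses[[id]] <- sim$timecourse
      truth[[id]] <- list(states = sim$states, spikes = sim$spikes)
      age <- round(min(95, max(60, stats::rnorm(1, spec$ageMean, spec$ageSd))), 1)
      rows[[id]] <- data.frame(
        subject_id = id, group = g, age = age,
        gender = ifelse(stats::runif(1) < spec$femaleProb, "F", "M"),
        study = ifelse(stats::runif(1) < spec$study2Prob, "study2", "study1"),
        seed = spec$seed, stringsAsFactors = FALSE)
    }
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject_id = character(0), group = character(0),
               age = numeric(0), gender = character(0),
               study = character(0), seed = integer(0))
  rownames(manifest) <- NULL
  list(timecourses = timecourses, manifest = manifest, truth = truth,
       model = model, spec = spec)
}

#' Write a simulated cohort to disk
#'
#' One TSV per subject (T rows x N columns with a header of network names),
#' a manifest CSV and a ground-truth JSON (latent sequences, spike positions).
#'
#' @param cohort result of [simulateCohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$timecourses)) {
    utils::write.table(tcData(cohort$timecourses[[id]]),
                       file.path(dir, paste0(id, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Majority-vote window labels from a latent state sequence
#'
#' Projects a per-time-point latent sequence onto sliding windows: each
#' window's label is the state with the largest total taper weight inside the
#' window (ties to the lower state index). Used to score window-level state
#' recovery against ground truth.
#'
#' @param states integer latent sequence (length T).
#' @param taper a `TaperSpec` from [makeTaper()].
#' @return integer vector of length `T - width + 1` (step 1).
#' @export
windowStateLabels <- function(states, taper) {
  w <- length(taper$weights)
  T <- length(states)
  stopifnot(T >= w)
  W <- windowCount(T, w, taper$step)
  starts <- seq(1L, by = taper$step, length.out = W)
  vapply(starts, function(s) {
    seg <- states[s:(s + w - 1)]
    tot <- tapply(taper$weights, seg, sum)
    as.integer(names(tot)[which.max(tot)])
  }, integer(1))
}

#' Label agreement after optimal state relabeling
#'
#' Maximum fraction of agreeing labels over all permutations of the k state
#' labels (cluster labels are arbitrary).
#'
#' @param estimated,truth integer label vectors of equal length.
#' @param k number of states.
#' @return accuracy in \[0, 1\].
#' @export
labelAccuracy <- function(estimated, truth, k) {
  stopifnot(length(estimated) == length(truth), k <= 8)
  perms <- permutations_int(k)
  best <- 0
  for (i in seq_len(nrow(perms))) {
    acc <- mean(perms[i, estimated] == truth)
    if (acc > best) best <- acc
  }
  best
}

# all permutations of 1..k as rows (k small)
permutations_int <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- permutations_int(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i) {
    rest <- setdiff(seq_len(k), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}
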