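#' @import methods
NULL

#' Per-subject network time courses
#'
#' Container for one subject's multivariate time course: a T x N matrix with
#' one column per network (e.g. resting-state network), sampled every `TR`
#' seconds.
#'
#' @slot data numeric T x N matrix, time in rows.
#' @slot TR sampling interval in seconds.
#' @slot networkNames character vector of length N.
#' @slot subjectId single character identifier.
#' @export
setClass("TimecourseSet",
  representation(
    data = "matrix",
    TR = "numeric",
    networkNames = "character",
    subjectId = "character"
  )
)

setValidity("TimecourseSet", function(object) {
  d <- object@data
  if (!is.numeric(d)) return("data must be numeric")
  if (nrow(d) < 2) return("need at least 2 time points")
  if (anyNA(d)) return("data contains missing values")
  if (length(object@TR) != 1 || object@TR <= 0) return("TR must be a positive scalar")
  if (length(object@networkNames) != ncol(d))
    return("networkNames length must equal ncol(data)")
  if (length(object@subjectId) != 1) return("subjectId must be a single string")
  TRUE
})

#' Construct a TimecourseSet
#'
#' @param data numeric T x N matrix.
#' @param TR sampling interval in seconds.
#' @param networkNames optional network labels (defaults to colnames or `N1..`).
#' @param subjectId subject identifier.
#' @return A [TimecourseSet-class] object.
#' @export
timecourseSet <- function(data, TR, networkNames = NULL, subjectId = "subject") {
  data <- as.matrix(data)
  if (is.null(networkNames)) {
    networkNames <- colnames(data)
    if (is.null(networkNames)) networkNames <- paste0("N", seq_len(ncol(data)))
  }
  colnames(data) <- networkNames
  new("TimecourseSet", data = data, TR = TR,
      networkNames = networkNames, subjectId = as.character(subjectId))
}

#' Latent connectivity-state model
#'
#' A set of N x N symmetric positive-definite matrices on the correlation
#' scale (unit diagonal), one per latent state; the generative counterpart of
#' the connectivity states recovered by clustering.
#'
#' @slot covariances list of N x N SPD matrices with unit diagonal.
#' @slot labels state names.
#' @export
setClass("StateModel",
  representation(covariances = "list", labels = "character")
)

setValidity("StateModel", function(object) {
  covs <- object@covariances
  if (length(covs) < 1) return("need at least one state")
  if (length(object@labels) != length(covs))
    return("labels length must equal number of states")
  for (s in seq_along(covs)) {
    C <- covs[[s]]
    if (!is.matrix(C) || nrow(C) != ncol(C))
      return(sprintf("state %d: covariance must be square", s))
    if (max(abs(C - t(C))) > 1e-8)
      return(sprintf("state %d: covariance not symmetric", s))
    if (max(abs(diag(C) - 1)) > 1e-8)
      return(sprintf("state %d: diagonal must be 1 (correlation scale)", s))
    ev <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 0)
      return(sprintf("state %d: not positive definite (min eigenvalue %.3g)", s, ev))
  }
  TRUE
})

#' Construct a StateModel
#' @param covariances list of SPD correlation-scale matrices.
#' @param labels optional state names.
#' @return A [StateModel-class] object.
#' @export
stateModel <- function(covariances, labels = NULL) {
  if (is.null(labels)) labels <- paste0("state", seq_along(covariances))
  new("StateModel", covariances = covariances, labels = labels)
}

#' First-order Markov chain specification
#'
#' @slot initialProbs probability vector over states.
#' @slot transitionMatrix row-stochastic matrix.
#' @export
setClass("MarkovSpec",
  representation(initialProbs = "numeric", transitionMatrix = "matrix")
)

setValidity("MarkovSpec", function(object) {
  p <- object@initialProbs
  P <- object@transitionMatrix
  k <- length(p)
  if (nrow(P) != k || ncol(P) != k) return("transitionMatrix must be k x k")
  if (any(p < 0) || abs(sum(p) - 1) > 1e-12) return("initialProbs must sum to 1")
  if (any(P < 0)) return("transition probabilities must be nonnegative")
  if (max(abs(rowSums(P) - 1)) > 1e-12) return("transition rows must sum to 1")
  TRUE
})

#' Construct a MarkovSpec
#' @param initialProbs probability vector (renormalized to sum exactly to 1).
#' @param transitionMatrix row-stochastic matrix (rows renormalized).
#' @return A [MarkovSpec-class] object.
#' @export
markovSpec <- function(initialProbs, transitionMatrix) {
  initialProbs <- initialProbs / sum(initialProbs)
  transitionMatrix <- transitionMatrix / rowSums(transitionMatrix)
  new("MarkovSpec", initialProbs = initialProbs,
      transitionMatrix = transitionMatrix)
}

#' Windowed connectivity matrices for one subject
#'
#' A stack of N x N matrices, one per sliding window, at a named processing
#' stage: `"covariance"` (tapered sample covariance), `"regularized"`
#' (graphical-LASSO covariance), `"z"` (Fisher z of the correlation) or
#' `"residualized"` (z after covariate regression).
#'
#' @slot matrices numeric array N x N x W.
#' @slot windowStarts integer start index of each window.
#' @slot stage processing stage label.
#' @slot lambda graphical-LASSO penalty used (NA before regularization).
#' @slot subjectId subject identifier.
#' @slot networkNames network labels.
#' @export
setClass("WindowedConnectivity",
  representation(
    matrices = "array",
    windowStarts = "integer",
    stage = "character",
    lambda = "numeric",
    subjectId = "character",
    networkNames = "character"
  )
)

setValidity("WindowedConnectivity", function(object) {
  a <- object@matrices
  if (length(dim(a)) != 3) return("matrices must be an N x N x W array")
  if (dim(a)[1] != dim(a)[2]) return("window matrices must be square")
  if (dim(a)[3] != length(object@windowStarts))
    return("windowStarts length must equal number of windows")
  if (!object@stage %in% c("covariance", "regularized", "z", "residualized"))
    return("unknown stage")
  if (length(object@networkNames) != dim(a)[1])
    return("networkNames length must equal matrix dimension")
  TRUE
})

#' k-means connectivity-state solution
#'
#' @slot k number of states.
#' @slot centroids k x P matrix (P = number of connection features).
#' @slot assignment integer state per row of the feature matrix.
#' @slot rowInfo data.frame with subject and window index per row.
#' @slot objective total L1 distance of rows to their assigned centroids.
#' @slot nInit number of random restarts used.
#' @slot seed RNG seed used.
#' @export
setClass("ClusterModel",
  representation(
    k = "integer",
    centroids = "matrix",
    assignment = "integer",
    rowInfo = "data.frame",
    objective = "numeric",
    nInit = "integer",
    seed = "integer"
  )
)

setValidity("ClusterModel", function(object) {
  if (nrow(object@centroids) != object@k) return("centroids must have k rows")
  if (length(object@assignment) != nrow(object@rowInfo))
    return("assignment length must match rowInfo")
  if (any(object@assignment < 1L) || any(object@assignment > object@k))
    return("assignments out of range")
  TRUE
})

setMethod("show", "TimecourseSet", function(object) {
  cat(sprintf("TimecourseSet '%s': %d time points x %d networks, TR = %g s\n",
              object@subjectId, nrow(object@data), ncol(object@data), object@TR))
})

setMethod("show", "StateModel", function(object) {
  cat(sprintf("StateModel with %d states (%s), %d networks\n",
              length(object@covariances),
              paste(object@labels, collapse = ", "),
              nrow(object@covariances[[1]])))
})

setMethod("show", "MarkovSpec", function(object) {
  cat(sprintf("MarkovSpec over %d states; self-transition probs: %s\n",
              length(object@initialProbs),
              paste(sprintf("%.3f", diag(object@transitionMatrix)), collapse = ", ")))
})

setMethod("show", "WindowedConnectivity", function(object) {
  d <- dim(object@matrices)
  cat(sprintf("WindowedConnectivity '%s': %d windows of %dx%d, stage '%s', lambda %s\n",
              object@subjectId, d[3], d[1], d[2], object@stage,
              ifelse(is.na(object@lambda), "-", format(object@lambda))))
})

setMethod("show", "ClusterModel", function(object) {
  cat(sprintf("ClusterModel: k = %d, %d windows, objective %.4g (%d restarts)\n",
              object@k, length(object@assignment), object@objective, object@nInit))
})

#' @describeIn TimecourseSet-class matrix of time courses
#' @param object a TimecourseSet.
#' @export
setGeneric("tcData", function(object) standardGeneric("tcData"))
#' @export
setMethod("tcData", "TimecourseSet", function(object) object@data)

#' @describeIn TimecourseSet-class sampling interval in seconds
#' @export
setGeneric("tcTR", function(object) standardGeneric("tcTR"))
#' @export
setMethod("tcTR", "TimecourseSet", function(object) object@TR)

#' Number of sliding windows held by an object
#' @param object a WindowedConnectivity.
#' @export
setGeneric("nWindows", function(object) standardGeneric("nWindows"))
#' @export
setMethod("nWindows", "WindowedConnectivity", function(object) dim(object@matrices)[3])

#' Window matrices as an N x N x W array
#' @param object a WindowedConnectivity.
#' @export
setGeneric("windowMatrices", function(object) standardGeneric("windowMatrices"))
#' @export
setMethod("windowMatrices", "WindowedConnectivity", function(object) object@matrices)

#' State assignments of a clustering solution
#' @param object a ClusterModel.
#' @export
setGeneric("stateAssignment", function(object) standardGeneric("stateAssignment"))
#' @export
setMethod("stateAssignment", "ClusterModel", function(object) object@assignment)

#' Centroid matrix of a clustering solution
#' @param object a ClusterModel.
#' @export
setGeneric("stateCentroids", function(object) standardGeneric("stateCentroids"))
#' @export
setMethod("stateCentroids", "ClusterModel", function(object) object@centroids)
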