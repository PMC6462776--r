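#' Read a subject manifest CSV
#'
#' @param path CSV with at least `subject_id` and `group` columns.
#' @return data.frame; errors on duplicate subject ids.
#' @export
readManifest <- function(path) {
  manifest <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "group") %in% names(manifest)))
    stop("manifest must have subject_id and group columns")
  dup <- manifest$subject_id[duplicated(manifest$subject_id)]
  if (length(dup))
    stop("duplicate subject ids in manifest: ", paste(unique(dup), collapse = ", "))
  manifest
}

#' Read per-subject time-course TSV files
#'
#' Expects one `<subject_id>.tsv` per manifest row (T rows x N columns with
#' a header of network names). Subjects missing a file are dropped with a
#' warning; files whose column count differs from the majority, or that
#' contain non-numeric cells, raise errors.
#'
#' @param dir directory of TSV files.
#' @param manifest data.frame from [readManifest()].
#' @param TR sampling interval in seconds.
#' @return named list of [TimecourseSet-class] objects.
#' @export
readTimecourses <- function(dir, manifest, TR = 3) {
  paths <- file.path(dir, paste0(manifest$subject_id, ".tsv"))
  present <- file.exists(paths)
  if (!any(present)) stop("no time-course files found in ", dir)
  if (any(!present))
    warning("missing time-course files for subjects: ",
            paste(manifest$subject_id[!present], collapse = ", "))
  out <- list()
  ncols <- integer(0)
  for (i in which(present)) {
    id <- manifest$subject_id[i]
    df <- tryCatch(utils::read.delim(paths[i], check.names = FALSE),
                   error = function(e) stop("empty or unreadable time-course file for subject ",
                                            id, call. = FALSE))
    if (nrow(df) == 0) stop("empty time-course file for subject ", id)
    nonNum <- which(!vapply(df, is.numeric, TRUE))
    if (length(nonNum))
      stop(sprintf("subject %s: non-numeric values in column(s) %s",
                   id, paste(names(df)[nonNum], collapse = ", ")))
    out[[id]] <- timecourseSet(as.matrix(df), TR = TR, subjectId = id)
    ncols[id] <- ncol(df)
  }
  if (length(unique(ncols)) > 1) {
    common <- as.integer(names(which.max(table(ncols))))
    bad <- names(ncols)[ncols != common]
    stop("inconsistent network counts across subjects; offenders: ",
         paste(bad, collapse = ", "))
  }
  extra <- setdiff(list.files(dir, pattern = "\\.tsv$"),
                   paste0(manifest$subject_id, ".tsv"))
  if (length(extra))
    warning("time-course files without manifest entry were excluded: ",
            paste(extra, collapse = ", "))
  out
}

#' Default run configuration
#'
#' Collects the tunable parameters of the full pipeline. All randomness is
#' routed through `seed`.
#'
#' @param windowWidth,windowSigma,windowStep taper parameters (TR units).
#' @param lambda `"cv"` or a fixed penalty.
#' @param lambdaGridN,lambdaMin,lambdaMax,lambdaFolds penalty-selection grid.
#' @param kRange candidate state counts; `k` fixes the count (NULL = elbow).
#' @param k fixed number of states, or NULL to select by elbow.
#' @param nInit k-means restarts.
#' @param minDensity,maxDensity,edgeStep efficiency density grid.
#' @param nPerm MANOVA permutations.
#' @param covariates manifest columns residualized out of the z values.
#' @param runNetdyn run the (expensive) efficiency-dynamics stage.
#' @param seed RNG seed recorded in every output.
#' @return list of class `RunConfig`.
#' @export
runConfig <- function(windowWidth = 22, windowSigma = 3, windowStep = 1,
                      lambda = "cv", lambdaGridN = 30, lambdaMin = 1e-3,
                      lambdaMax = 1, lambdaFolds = 20, kRange = 2:8, k = NULL,
                      nInit = 500, minDensity = 0.037, maxDensity = 0.393,
                      edgeStep = 1, nPerm = 9999,
                      covariates = c("age", "gender", "study"),
                      runNetdyn = TRUE, seed = 1) {
  cfg <- list(windowWidth = windowWidth, windowSigma = windowSigma,
              windowStep = windowStep, lambda = lambda,
              lambdaGridN = lambdaGridN, lambdaMin = lambdaMin,
              lambdaMax = lambdaMax, lambdaFolds = lambdaFolds,
              kRange = kRange, k = k, nInit = nInit,
              minDensity = minDensity, maxDensity = maxDensity,
              edgeStep = edgeStep, nPerm = nPerm, covariates = covariates,
              runNetdyn = runNetdyn, seed = as.integer(seed))
  stopifnot(cfg$windowWidth >= 2, cfg$windowSigma > 0, cfg$windowStep >= 1,
            cfg$lambdaMin > 0, cfg$lambdaMax > cfg$lambdaMin,
            cfg$lambdaFolds >= 2, cfg$nInit >= 1)
  class(cfg) <- "RunConfig"
  cfg
}

#' Read a run configuration from YAML or JSON
#'
#' Keys not present fall back to the [runConfig()] defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A `RunConfig`.
#' @export
readRunConfig <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
          else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(runConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(runConfig, vals)
}
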