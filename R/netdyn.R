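#' Maximum number of edges of an undirected graph on N nodes
#' @param N number of nodes (>= 2).
#' @return `N (N - 1) / 2`; 351 for N = 27.
#' @export
maxEdges <- function(N) {
  if (N < 2) stop("need at least 2 nodes")
  as.integer(N * (N - 1) / 2)
}

#' Edge-density grid as integer edge counts
#'
#' Every integer edge count between `round(minDensity * maxEdges)` and
#' `round(maxDensity * maxEdges)`. The default 3.7%-39.3% range on 27 nodes
#' gives edge counts 13 through 138.
#'
#' @param nNetworks number of nodes.
#' @param minDensity,maxDensity density range in (0, 1\].
#' @param edgeStep stride through the integer edge counts (1 = every count).
#' @return list with `densities`, `edgeCounts`, `maxEdges`.
#' @export
densityGrid <- function(nNetworks = 27, minDensity = 0.037, maxDensity = 0.393,
                        edgeStep = 1) {
  M <- maxEdges(nNetworks)
  lo <- max(1L, round(minDensity * M))
  hi <- round(maxDensity * M)
  stopifnot(hi >= lo)
  counts <- seq.int(lo, hi, by = edgeStep)
  list(densities = counts / M, edgeCounts = as.integer(counts), maxEdges = M)
}

#' Binarize a connectivity matrix at a target edge density
#'
#' Keeps the `m = round(density * maxEdges)` largest off-diagonal entries by
#' absolute value as edges of an undirected, unweighted graph. Ties at the
#' cutoff are broken deterministically by (row, col) lexicographic order.
#'
#' @param mat symmetric matrix.
#' @param density target edge density in (0, 1\].
#' @return symmetric 0/1 adjacency matrix with zero diagonal.
#' @export
thresholdToDensity <- function(mat, density) {
  N <- nrow(mat)
  stopifnot(ncol(mat) == N, density > 0, density <= 1)
  M <- maxEdges(N)
  m <- round(density * M)
  if (m == 0) stop("density too low: zero edges requested")
  pairs <- utPairs(N)
  vals <- abs(mat[pairs])
  ord <- order(-vals, pairs[, 1], pairs[, 2])
  keep <- pairs[ord[seq_len(m)], , drop = FALSE]
  A <- matrix(0L, N, N)
  A[keep] <- 1L
  A + t(A)
}

#' All-pairs shortest-path lengths of a binary graph
#'
#' Unweighted geodesic distances by vectorized breadth-first search
#' (boolean adjacency powers); unreachable pairs are `Inf`.
#'
#' @param adj symmetric 0/1 adjacency matrix with zero diagonal.
#' @return N x N distance matrix (0 on the diagonal).
#' @export
graphDistances <- function(adj) {
  N <- nrow(adj)
  D <- matrix(Inf, N, N)
  diag(D) <- 0
  D[adj != 0] <- 1
  reach <- adj != 0
  for (step in 2:max(2, N)) {
    if (!any(is.infinite(D[upper.tri(D)]))) break
    reach <- (reach %*% adj) != 0
    new <- reach & is.infinite(D)
    if (!any(new)) break
    D[new] <- step
  }
  D
}

#' Global efficiency of a binary graph
#'
#' Mean over ordered node pairs of the inverse shortest-path length, with
#' disconnected pairs contributing 0. Equals 1 for the complete graph and 0
#' for the empty graph.
#'
#' @param adj symmetric 0/1 adjacency matrix.
#' @return efficiency in \[0, 1\].
#' @export
globalEfficiency <- function(adj) {
  N <- nrow(adj)
  if (N < 2) return(0)
  D <- graphDistances(adj)
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv) / (N * (N - 1))
}

#' Local efficiency of a binary graph
#'
#' Per node, the global efficiency of the subgraph induced by the node's
#' neighbors; nodes with fewer than 2 neighbors score 0.
#'
#' @param adj symmetric 0/1 adjacency matrix.
#' @return list with `perNode` and `mean`.
#' @export
localEfficiency <- function(adj) {
  N <- nrow(adj)
  perNode <- vapply(seq_len(N), function(i) {
    nb <- which(adj[i, ] != 0)
    if (length(nb) < 2) return(0)
    globalEfficiency(adj[nb, nb, drop = FALSE])
  }, numeric(1))
  list(perNode = perNode, mean = mean(perNode))
}

# density-grid-averaged efficiencies of one connectivity matrix
gridEfficiency <- function(mat, grid) {
  M <- grid$maxEdges
  eg <- el <- numeric(length(grid$edgeCounts))
  N <- nrow(mat)
  pairs <- utPairs(N)
  vals <- abs(mat[pairs])
  ord <- order(-vals, pairs[, 1], pairs[, 2])
  for (i in seq_along(grid$edgeCounts)) {
    keep <- pairs[ord[seq_len(grid$edgeCounts[i])], , drop = FALSE]
    A <- matrix(0L, N, N)
    A[keep] <- 1L
    A <- A + t(A)
    eg[i] <- globalEfficiency(A)
    el[i] <- localEfficiency(A)$mean
  }
  c(eg = mean(eg), el = mean(el))
}

#' Time-resolved, density-integrated graph efficiency
#'
#' For every window, graphs are binarized at each density of the grid, the
#' global and (mean) local efficiencies are computed and averaged across the
#' grid (arithmetic mean); temporal variability is the SD over windows
#' (denominator W - 1).
#'
#' @param wc a [WindowedConnectivity-class] with >= 2 windows (the absolute
#'   values of the window matrices are thresholded; z and r rank
#'   identically).
#' @param grid a [densityGrid()].
#' @return list with `eg`, `el` (per-window series), `sdEg`, `sdEl`.
#' @export
efficiencyDynamics <- function(wc, grid = densityGrid(length(wc@networkNames))) {
  stopifnot(is(wc, "WindowedConnectivity"))
  W <- nWindows(wc)
  if (W < 2) stop("need at least 2 windows for efficiency variability")
  eff <- vapply(seq_len(W),
                function(i) gridEfficiency(wc@matrices[, , i], grid),
                numeric(2))
  list(eg = eff["eg", ], el = eff["el", ],
       sdEg = stats::sd(eff["eg", ]), sdEl = stats::sd(eff["el", ]))
}

#' Static density-integrated efficiency from the whole time course
#'
#' Correlation over the full time course, thresholded at each density of the
#' grid; efficiencies averaged over the grid.
#'
#' @param tc a [TimecourseSet-class] with T >= 3.
#' @param grid a [densityGrid()].
#' @return list with `eg` and `el`.
#' @export
staticEfficiency <- function(tc, grid = densityGrid(ncol(tcData(tc)))) {
  X <- tcData(tc)
  stopifnot(nrow(X) >= 3)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant time course for network: ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  R <- stats::cor(X)
  e <- gridEfficiency(R, grid)
  list(eg = unname(e["eg"]), el = unname(e["el"]))
}
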