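#' @include AllClasses.R
NULL

#' Split a signed weight matrix into excitatory and inhibitory networks
#'
#' Positive coefficients (excitatory causal effects) go to the excitatory
#' matrix unchanged; negative coefficients (inhibitory effects) go to the
#' inhibitory matrix as their magnitudes. Exact partition: excitatory
#' minus inhibitory (signs restored) reproduces the input.
#'
#' @param x A \code{\link{SignedWeightedNetwork-class}}.
#' @return List with \code{excitatory} and \code{inhibitory}
#'   \code{SignedWeightedNetwork} objects (both nonnegative).
#' @export
splitBySign <- function(x) {
  stopifnot(is(x, "SignedWeightedNetwork"))
  w <- weightMatrix(x)
  list(excitatory = SignedWeightedNetwork(pmax(w, 0)),
       inhibitory = SignedWeightedNetwork(pmax(-w, 0)))
}

## Criteria check for a retained arc set. Returns largest weak component
## membership and the minimum skeleton degree inside it.
.pruneCriteria <- function(idx, k, n) {
  keep <- idx[seq_len(k), , drop = FALSE]
  g <- igraph::graph_from_edgelist(keep, directed = TRUE)
  if (igraph::vcount(g) < n)
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
  comp <- igraph::components(g, mode = "weak")
  big <- which.max(comp$csize)
  members <- which(comp$membership == big)
  gu <- igraph::as_undirected(g, mode = "collapse")
  degs <- igraph::degree(gu)[members]
  list(componentSize = max(comp$csize), minDegree = min(degs))
}

#' Proportional threshold pruning of a weighted network
#'
#' Retains the smallest proportion \eqn{p} of the largest-magnitude
#' weights, binarized as arcs, such that (i) at least
#' \code{ceiling(connectFraction * N)} vertices belong to the largest
#' weakly connected component and (ii) every vertex inside that component
#' has undirected skeleton degree (number of distinct neighbors) at least
#' \code{degreeFactor * log(N)}. Ties in weight magnitude are broken by
#' (row, column) order, so the retained arc set is monotone in \eqn{p}
#' and the minimal \eqn{p} is found by a grid scan (0.5\% steps) refined
#' by bisection down to single-arc granularity. Vertices outside the
#' largest component (at most the allowed 1\%) are exempt from the degree
#' criterion, which would otherwise be jointly unsatisfiable whenever a
#' vertex is disconnected.
#'
#' @param x A nonnegative \code{SignedWeightedNetwork} (apply
#'   \code{\link{splitBySign}} first).
#' @param connectFraction Minimum fraction of vertices in the largest
#'   weak component; default 0.99.
#' @param degreeFactor Multiplier of \eqn{\ln N} for the minimum degree;
#'   default 2.
#' @param gridStep Grid resolution of the initial scan over \eqn{p};
#'   default 0.005.
#' @return List with \code{network} (the pruned
#'   \code{\link{DirectedNetwork-class}}), \code{p} (retained proportion
#'   of nonzero weights), \code{k} (retained arc count), and
#'   \code{criteria} (achieved component size and minimum degree, plus
#'   the required bounds).
#' @export
pruneNetwork <- function(x, connectFraction = 0.99, degreeFactor = 2.0,
                         gridStep = 0.005) {
  stopifnot(is(x, "SignedWeightedNetwork"))
  w <- weightMatrix(x)
  if (any(w < 0))
    stop("pruning expects nonnegative weights; apply splitBySign first",
         call. = FALSE)
  n <- nrow(w)
  if (n < 3L)
    stop("at least 3 vertices required", call. = FALSE)
  nz <- which(w > 0, arr.ind = TRUE)
  M <- nrow(nz)
  if (M == 0L)
    stop("no nonzero weights to retain", call. = FALSE)
  ## deterministic order: decreasing magnitude, ties by (row, column)
  ord <- order(-w[nz], nz[, 1L], nz[, 2L])
  idx <- nz[ord, , drop = FALSE]
  needComp <- ceiling(connectFraction * n)
  needDeg <- degreeFactor * log(n)
  feasible <- function(k) {
    cr <- .pruneCriteria(idx, k, n)
    cr$componentSize >= needComp && cr$minDegree >= needDeg
  }
  ## grid scan for the first feasible proportion
  ks <- unique(pmin(M, ceiling(seq(gridStep, 1, by = gridStep) * M)))
  if (M %in% ks == FALSE) ks <- c(ks, M)
  hit <- NA_integer_
  lo <- 0L
  for (k in ks) {
    if (feasible(k)) { hit <- k; break }
    lo <- k
  }
  if (is.na(hit)) {
    best <- .pruneCriteria(idx, M, n)
    stop("pruning infeasible: with all ", M, " weights retained, largest ",
         "component has ", best$componentSize, " of the required ",
         needComp, " vertices and minimum degree ", best$minDegree,
         " (required ", format(needDeg, digits = 4), ")", call. = FALSE)
  }
  ## bisect (lo infeasible, hit feasible) to single-arc granularity
  while (hit - lo > 1L) {
    mid <- (hit + lo) %/% 2L
    if (feasible(mid)) hit <- mid else lo <- mid
  }
  ## guard against non-monotone edge cases: walk down while still feasible
  while (hit > 1L && feasible(hit - 1L)) hit <- hit - 1L
  keep <- idx[seq_len(hit), , drop = FALSE]
  net <- DirectedNetwork(keep, labels = rownames(w))
  achieved <- .pruneCriteria(idx, hit, n)
  list(network = net, p = hit / M, k = hit,
       criteria = list(componentSize = achieved$componentSize,
                       requiredComponentSize = needComp,
                       minDegree = achieved$minDegree,
                       requiredMinDegree = needDeg))
}
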