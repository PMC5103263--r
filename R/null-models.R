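#' @include signatures.R
NULL

## Unordered connected pairs (the undirected skeleton) of a network.
.skeletonPairs <- function(x) {
  U <- adjacencyMatrix(x)
  U <- (U + t(U)) > 0
  which(U & upper.tri(U), arr.ind = TRUE)
}

#' Direction-randomization null model
#'
#' Destroys edge-direction information while exactly preserving the
#' undirected skeleton (and hence the edge density): every connected
#' unordered pair is independently reassigned one of the three states —
#' pure \eqn{i \to j}, pure \eqn{j \to i}, or reciprocal — each with
#' probability one third.
#'
#' @param x A \code{DirectedNetwork}.
#' @param seed Optional integer seed for reproducibility; when
#'   \code{NULL} the current RNG state is used.
#' @return A \code{DirectedNetwork} on the same labels with the same
#'   skeleton and randomized directions.
#' @export
#' @seealso \code{\link{flipExpectation}}, \code{\link{convergenceCheck}}
flipDirections <- function(x, seed = NULL) {
  stopifnot(is(x, "DirectedNetwork"))
  if (!is.null(seed)) set.seed(seed)
  pairs <- .skeletonPairs(x)
  m <- nrow(pairs)
  if (m == 0L)
    return(DirectedNetwork(labels = vertexLabels(x)))
  state <- sample.int(3L, m, replace = TRUE)  # 1: i->j, 2: j->i, 3: both
  from <- c(pairs[state != 2L, 1L], pairs[state != 1L, 2L])
  to <- c(pairs[state != 2L, 2L], pairs[state != 1L, 1L])
  DirectedNetwork(cbind(from, to), labels = vertexLabels(x))
}

#' Analytic expectation under the direction-flip null
#'
#' Expected normalized signature blocks when every skeleton edge takes
#' one of the three orientation states uniformly and independently. The
#' class probabilities are derived in code by exhaustive enumeration of
#' the equiprobable orientation assignments (the labeled-type class sizes
#' of the wedge and triangle enumerations), not hard-coded: the degree
#' block is uniform (1/3 each); the wedge block is the 9 center
#' assignments partitioned over the 6 classes; the triangle block is the
#' 27 edge assignments partitioned over the 7 classes.
#'
#' @param x Optional \code{DirectedNetwork}; when supplied, the expected
#'   raw per-vertex counts are also returned, computed from the
#'   undirected skeleton (degree / 3 per type; undirected induced wedge
#'   and triangle counts at each vertex times the class probabilities).
#' @return List with \code{degree}, \code{wedge}, \code{triangle}
#'   (probability vectors, each summing to 1) and, when \code{x} is
#'   given, \code{perVertex} (a data frame of expected raw counts).
#' @export
flipExpectation <- function(x = NULL) {
  enum <- enumerateConnectedDigraphs(3L)
  wedge <- enum$nTypes[match(.WEDGE_CLASSES, enum$class)]
  triangle <- enum$nTypes[match(.TRIANGLE_CLASSES, enum$class)]
  out <- list(degree = .named(rep(1, 3) / 3, c("d_out", "d_in", "d_rec")),
              wedge = .named(wedge / sum(wedge), .WEDGE_CLASSES),
              triangle = .named(triangle / sum(triangle),
                                .TRIANGLE_CLASSES))
  if (!is.null(x)) {
    stopifnot(is(x, "DirectedNetwork"))
    U <- adjacencyMatrix(x)
    U <- (U + t(U) > 0) + 0
    deg <- rowSums(U)
    trianglesAt <- diag(U %*% U %*% U) / 2
    wedgesAt <- choose(deg, 2) - trianglesAt
    perVertex <- cbind(
      matrix(deg / 3, ncol = 3L, nrow = length(deg)),
      outer(wedgesAt, out$wedge),
      outer(trianglesAt, out$triangle))
    dimnames(perVertex) <- list(vertexLabels(x), .SIGNATURE_NAMES)
    out$perVertex <- as.data.frame(perVertex)
  }
  out
}

#' Monte-Carlo convergence of flipped signatures to the analytic null
#'
#' Averages block-normalized signature vectors over \code{reps}
#' independent direction flips of the network and compares each of the 16
#' components with the analytic expectation, in standard-error units.
#' Under the flip null each vertex's block denominators (total degree,
#' undirected wedge count, undirected triangle count) are constant across
#' flips, so the normalized ensemble means are unbiased for the class
#' probabilities. Blocks that are zero for every vertex (e.g. a
#' triangle-free skeleton) are reported degenerate and not compared.
#'
#' @param x A \code{DirectedNetwork}.
#' @param reps Number of independent flips (\eqn{\ge 1}).
#' @param seed Optional integer seed.
#' @return Data frame with one row per signature component: \code{class},
#'   \code{mean} (ensemble mean of the network-average normalized
#'   signature), \code{expected}, \code{se} (standard error over reps)
#'   and \code{z} (deviation in SE units; \code{NA} for degenerate
#'   components).
#' @export
convergenceCheck <- function(x, reps, seed = NULL) {
  stopifnot(is(x, "DirectedNetwork"), reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  expectation <- flipExpectation()
  expected <- c(expectation$degree, expectation$wedge,
                expectation$triangle)
  blocks <- list(degree = 1:3, wedge = 4:9, triangle = 10:16)
  samples <- matrix(NA_real_, reps, 16L,
                    dimnames = list(NULL, .SIGNATURE_NAMES))
  for (r in seq_len(reps)) {
    g <- flipDirections(x)
    cnt <- signatureCounts(signatureMatrix(g))
    netMean <- numeric(16L)
    for (b in blocks) {
      tot <- rowSums(cnt[, b, drop = FALSE])
      live <- tot > 0
      netMean[b] <- if (any(live))
        colMeans(cnt[live, b, drop = FALSE] / tot[live])
      else NA_real_
    }
    samples[r, ] <- netMean
  }
  mn <- colMeans(samples)
  se <- apply(samples, 2L, stats::sd) / sqrt(reps)
  z <- (mn - expected) / se
  z[!is.finite(z)] <- NA_real_
  data.frame(class = .SIGNATURE_NAMES, mean = mn, expected = expected,
             se = se, z = z, row.names = NULL)
}
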