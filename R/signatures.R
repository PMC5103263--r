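#' @include oracle.R
NULL

## ---------------------------------------------------------------------------
## Typed counts (fast path: typed-adjacency matrix products)
## ---------------------------------------------------------------------------

## All-vertex degree matrix: n x 3 (out, in, rec).
.degreeMatrix <- function(ta) {
  cbind(out = rowSums(ta$out), `in` = rowSums(ta$`in`),
        rec = rowSums(ta$rec))
}

## All-vertex typed wedge counts: n x 3 x 3 array W[i, alpha, beta] of
## induced (alpha, beta) wedges centered at i, counted over ordered
## neighbor pairs (h, j). Raw product count minus same-type diagonal pairs
## minus closed (adjacent h-j) pairs.
.typedWedgeArray <- function(ta) {
  d <- .degreeMatrix(ta)
  n <- nrow(d)
  U <- ta$out + ta$`in` + ta$rec  # undirected skeleton (0/1, symmetric)
  W <- array(0, c(n, 3L, 3L),
             dimnames = list(NULL, .EDGE_TYPES, .EDGE_TYPES))
  AU <- lapply(ta, function(A) A %*% U)
  for (a in .EDGE_TYPES) for (b in .EDGE_TYPES) {
    closed <- rowSums(AU[[a]] * ta[[b]])
    W[, a, b] <- d[, a] * d[, b] - (a == b) * d[, a] - closed
  }
  W
}

## All-vertex typed triangle counts: n x 3 x 3 x 3 array T[i, a, b, g] =
## number of ordered pairs (h, j) with h an a-neighbor of i, j a
## g-neighbor of i, and the h-j edge of type b with respect to j:
##   T(a, b, g)_i = sum_j A_g(i, j) * (A_a %*% t(A_b))(i, j).
.typedTriangleArray <- function(ta) {
  n <- nrow(ta$out)
  Tt <- array(0, c(n, 3L, 3L, 3L),
              dimnames = list(NULL, .EDGE_TYPES, .EDGE_TYPES, .EDGE_TYPES))
  for (a in .EDGE_TYPES) for (b in .EDGE_TYPES) {
    P <- ta[[a]] %*% t(ta[[b]])
    for (g in .EDGE_TYPES)
      Tt[, a, b, g] <- rowSums(P * ta[[g]])
  }
  Tt
}

#' Per-vertex 2-node graphlet (degree) counts
#'
#' The numbers of out-, in-, and reciprocal 2-node graphlets starting at a
#' vertex, i.e. the cardinalities of its three typed neighbor sets.
#'
#' @param x A \code{DirectedNetwork}.
#' @param i Vertex label or index.
#' @return Named numeric vector \code{c(d_out, d_in, d_rec)}.
#' @export
degreeCounts <- function(x, i) {
  stopifnot(is(x, "DirectedNetwork"))
  idx <- .resolveVertex(vertexLabels(x), i)
  d <- .degreeMatrix(typedAdjacency(x))[idx, ]
  .named(as.numeric(d), c("d_out", "d_in", "d_rec"))
}

#' Typed induced wedge counts of a vertex
#'
#' \eqn{W_i(\alpha, \beta)}: the number of ordered pairs \eqn{(h, j)} of
#' distinct vertices with \eqn{h} an \eqn{\alpha}-neighbor and \eqn{j} a
#' \eqn{\beta}-neighbor of \eqn{i}, such that \eqn{h} and \eqn{j} are not
#' adjacent in either direction — only induced wedge graphlets centered at
#' \eqn{i} are counted, so every closed (triangle) pair is excluded. By
#' symmetry \eqn{W_i(\alpha, \beta) = W_i(\beta, \alpha)}.
#'
#' @param x A \code{DirectedNetwork}.
#' @param i Vertex label or index.
#' @return Numeric 3 x 3 matrix with rows \eqn{\alpha} and columns
#'   \eqn{\beta} over the types \code{out}, \code{in}, \code{rec}.
#' @export
typedWedgeCounts <- function(x, i) {
  stopifnot(is(x, "DirectedNetwork"))
  idx <- .resolveVertex(vertexLabels(x), i)
  W <- .typedWedgeArray(typedAdjacency(x))
  matrix(W[idx, , ], 3L, 3L, dimnames = list(.EDGE_TYPES, .EDGE_TYPES))
}

#' Typed triangle counts of a vertex
#'
#' \eqn{T_i(\alpha, \beta, \gamma)}: the number of ordered pairs
#' \eqn{(h, j)} forming a triangle with \eqn{i} in which the \eqn{i}-\eqn{h}
#' edge has type \eqn{\alpha} and the \eqn{i}-\eqn{j} edge type
#' \eqn{\gamma}, both with respect to \eqn{i}, and the \eqn{h}-\eqn{j}
#' edge has type \eqn{\beta} with respect to \eqn{j}. For example the
#' triangle \eqn{\{i \to h, h \to j, i \leftrightarrow j\}} is the
#' (out, in, rec) — in the field's symbols \eqn{(+, -, \circ)} — triangle.
#'
#' @param x A \code{DirectedNetwork}.
#' @param i Vertex label or index.
#' @return Numeric 3 x 3 x 3 array indexed \eqn{[\alpha, \beta, \gamma]}.
#' @export
typedTriangleCounts <- function(x, i) {
  stopifnot(is(x, "DirectedNetwork"))
  idx <- .resolveVertex(vertexLabels(x), i)
  Tt <- .typedTriangleArray(typedAdjacency(x))
  array(Tt[idx, , , ], c(3L, 3L, 3L),
        dimnames = list(.EDGE_TYPES, .EDGE_TYPES, .EDGE_TYPES))
}

## ---------------------------------------------------------------------------
## Class reduction
## ---------------------------------------------------------------------------

## n x 6 wedge class counts from the typed wedge array. Same-type counts
## are over ordered pairs, hence halved (evenness asserted); mixed-type
## classes take one representative ordering.
.wedgeClassMatrix <- function(W) {
  even <- function(v, what) {
    if (any(v %% 2 != 0))
      stop("internal consistency error: odd ordered-pair count for ", what,
           call. = FALSE)
    v / 2
  }
  out <- cbind(
    W_out     = even(W[, "out", "out"], "W_out"),
    W_in      = even(W[, "in", "in"], "W_in"),
    W_path    = W[, "out", "in"],
    W_out_rec = W[, "out", "rec"],
    W_in_rec  = W[, "in", "rec"],
    W_rec     = even(W[, "rec", "rec"], "W_rec"))
  out
}

## n x 7 triangle class counts from the typed triangle array. Every
## triangle containing i is visited by exactly two ordered (h, j)
## assignments, each contributing to one typed tuple of the same
## isomorphism class, so class sums are halved (evenness asserted).
.triangleClassMatrix <- function(Tt) {
  map <- .triangleTupleClassMap()
  n <- dim(Tt)[1L]
  out <- matrix(0, n, 7L, dimnames = list(NULL, .TRIANGLE_CLASSES))
  for (a in .EDGE_TYPES) for (b in .EDGE_TYPES) for (g in .EDGE_TYPES)
    out[, map[a, b, g]] <- out[, map[a, b, g]] + Tt[, a, b, g]
  if (any(out %% 2 != 0))
    stop("internal consistency error: odd typed triangle class sum",
         call. = FALSE)
  out / 2
}

#' Wedge isomorphism-class counts of a vertex
#'
#' The number of distinct induced wedges centered at \code{i} in each of
#' the six wedge isomorphism classes. Each wedge is counted exactly once,
#' at its center; wedge endpoints accumulate nothing.
#'
#' @param x A \code{DirectedNetwork}.
#' @param i Vertex label or index.
#' @return Named numeric vector over the six wedge classes.
#' @export
wedgeClassCounts <- function(x, i) {
  stopifnot(is(x, "DirectedNetwork"))
  idx <- .resolveVertex(vertexLabels(x), i)
  W <- .typedWedgeArray(typedAdjacency(x))
  .named(as.numeric(.wedgeClassMatrix(W)[idx, ]), .WEDGE_CLASSES)
}

#' Triangle isomorphism-class counts of a vertex
#'
#' The number of distinct triangles containing \code{i} (in any position)
#' in each of the seven triangle isomorphism classes: transitive
#' (\code{T_acyclic}), directed cycle (\code{T_cycle}), one reciprocal
#' dyad with the third vertex sending to both (\code{T_out_rec}),
#' receiving from both (\code{T_in_rec}), or sending to one member and
#' receiving from the other (\code{T_cycle_rec}), two reciprocal dyads
#' plus a pure arc (\code{T_cycle_rec2}), and three reciprocal dyads
#' (\code{T_rec}).
#'
#' @param x A \code{DirectedNetwork}.
#' @param i Vertex label or index.
#' @return Named numeric vector over the seven triangle classes.
#' @export
triangleClassCounts <- function(x, i) {
  stopifnot(is(x, "DirectedNetwork"))
  idx <- .resolveVertex(vertexLabels(x), i)
  Tt <- .typedTriangleArray(typedAdjacency(x))
  .named(as.numeric(.triangleClassMatrix(Tt)[idx, ]), .TRIANGLE_CLASSES)
}

## ---------------------------------------------------------------------------
## Signature vectors and matrices
## ---------------------------------------------------------------------------

#' Signature vector of a vertex
#'
#' The 16-dimensional feature vector \eqn{F_i = [d_i, W_i, T_i]}: the
#' three 2-node degrees, the six wedge-class counts and the seven
#' triangle-class counts of graphlets starting at \code{i}, in the fixed
#' order of \code{\link{signatureClassNames}}.
#'
#' @param x A \code{DirectedNetwork}.
#' @param i Vertex label or index.
#' @return Named numeric vector of length 16.
#' @export
signatureVector <- function(x, i) {
  stopifnot(is(x, "DirectedNetwork"))
  idx <- .resolveVertex(vertexLabels(x), i)
  signatureCounts(signatureMatrix(x))[idx, ]
}

#' Signature matrix of a network
#'
#' Stacks the signature vectors of all vertices into the \eqn{N \times 16}
#' signature matrix, rows in vertex label order. Computed for all vertices
#' at once via typed-adjacency matrix products (dense \eqn{O(n^3)}).
#'
#' @param x A \code{DirectedNetwork}.
#' @param ... Unused.
#' @return A \code{\link{SignatureMatrix-class}}.
#' @aliases signatureMatrix
#' @export
#' @examples
#' g <- DirectedNetwork(cbind(c("a", "b", "c"), c("b", "c", "a")))
#' signatureCounts(signatureMatrix(g))  # each vertex closes one cycle
setMethod("signatureMatrix", "DirectedNetwork", function(x, ...) {
  ta <- typedAdjacency(x)
  d <- .degreeMatrix(ta)
  colnames(d) <- c("d_out", "d_in", "d_rec")
  W <- .wedgeClassMatrix(.typedWedgeArray(ta))
  Tr <- .triangleClassMatrix(.typedTriangleArray(ta))
  counts <- cbind(d, W, Tr)
  dimnames(counts) <- list(vertexLabels(x), .SIGNATURE_NAMES)
  new("SignatureMatrix", counts = counts)
})

#' Block-normalized signature vector
#'
#' Normalizes the three blocks of a signature vector separately: degrees
#' by total degree, wedge classes by total wedge count, triangle classes
#' by total triangle count. A block summing to zero maps to all-zero
#' fractions and is flagged degenerate rather than raising an error.
#'
#' @param f Numeric signature vector of length 16 (see
#'   \code{\link{signatureVector}}).
#' @return Numeric vector of 16 fractions with attribute
#'   \code{"degenerate"}: a named logical over \code{degree},
#'   \code{wedge}, \code{triangle}.
#' @export
normalizedSignature <- function(f) {
  f <- as.numeric(f)
  stopifnot(length(f) == 16L)
  blocks <- list(degree = 1:3, wedge = 4:9, triangle = 10:16)
  out <- numeric(16L)
  degenerate <- vapply(blocks, function(ix) {
    s <- sum(f[ix])
    if (s > 0) out[ix] <<- f[ix] / s
    s == 0
  }, logical(1L))
  out <- .named(out, .SIGNATURE_NAMES)
  attr(out, "degenerate") <- degenerate
  out
}

#' Write a signature matrix as TSV
#'
#' One row per vertex: a \code{vertex} label column followed by the 16
#' named count columns.
#'
#' @param x A \code{SignatureMatrix}.
#' @param path Destination path.
#' @param header Optional comment lines written first (prefixed
#'   \code{# }).
#' @return Invisibly, \code{path}.
#' @export
writeSignatureMatrix <- function(x, path, header = NULL) {
  stopifnot(is(x, "SignatureMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header))
    writeLines(paste("#", header), con)
  df <- data.frame(vertex = vertexLabels(x), signatureCounts(x),
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a signature matrix from TSV
#'
#' @param path Path to a TSV written by \code{\link{writeSignatureMatrix}}.
#' @return A \code{\link{SignatureMatrix-class}}.
#' @export
readSignatureMatrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          comment.char = "#", check.names = FALSE)
  if (!identical(colnames(df), c("vertex", .SIGNATURE_NAMES)))
    stop("not a signature matrix TSV: unexpected columns", call. = FALSE)
  counts <- as.matrix(df[, .SIGNATURE_NAMES])
  rownames(counts) <- as.character(df$vertex)
  new("SignatureMatrix", counts = counts)
}
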