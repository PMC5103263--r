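#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## DirectedNetwork
## ---------------------------------------------------------------------------

#' DirectedNetwork: a simple directed graph with reciprocal-edge typing
#'
#' A simple directed (unweighted) graph \eqn{G = (V, E)} with no self-arcs
#' and no duplicate arcs. An opposite pair of arcs \eqn{\{(i,j),(j,i)\}} is
#' treated as a single reciprocal edge, so every adjacent ordered pair has
#' exactly one of three types with respect to its first vertex: out
#' (\eqn{i \to j} only), in (\eqn{j \to i} only), or reciprocal
#' (\eqn{i \leftrightarrow j}).
#'
#' @slot labels Character vector of vertex labels (unique, in index order).
#' @slot arcs Integer matrix with two columns (\code{from}, \code{to});
#'   one row per ordered arc. A reciprocal edge is stored as both rows.
#'
#' @param x A \code{DirectedNetwork}.
#' @aliases numVertices vertexLabels arcs
#' @seealso \code{\link{readEdgeList}}, \code{\link{typedAdjacency}},
#'   \code{\link{signatureMatrix}}
#' @export
setClass("DirectedNetwork",
         representation(labels = "character", arcs = "matrix"))

setValidity("DirectedNetwork", function(object) {
  n <- length(object@labels)
  a <- object@arcs
  msg <- character()
  if (anyDuplicated(object@labels))
    msg <- c(msg, "vertex labels must be unique")
  if (!is.integer(a) || ncol(a) != 2L)
    msg <- c(msg, "arcs must be an integer matrix with 2 columns")
  else if (nrow(a) > 0L) {
    if (any(a < 1L) || any(a > n))
      msg <- c(msg, "arc endpoints out of vertex range")
    if (any(a[, 1L] == a[, 2L]))
      msg <- c(msg, "self-arcs are excluded")
    if (anyDuplicated(a))
      msg <- c(msg, "duplicate arcs are not allowed")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a DirectedNetwork
#'
#' @param arcs Two-column matrix or data frame of ordered arcs, either
#'   integer vertex indices or character labels. Duplicate rows are
#'   removed; an opposite pair of rows becomes one reciprocal edge.
#' @param labels Character vector of vertex labels. Required when
#'   \code{arcs} is an index matrix; optional (extended by first
#'   appearance) when arcs carry labels.
#' @param n Number of vertices; defaults to \code{length(labels)}.
#'
#' @return A \code{DirectedNetwork} object.
#' @export
#' @examples
#' g <- DirectedNetwork(cbind(c("a", "b"), c("b", "a")))
#' edgeTypeSummary(g)  # one reciprocal dyad
DirectedNetwork <- function(arcs = NULL, labels = NULL, n = NULL) {
  if (is.null(arcs) || NROW(arcs) == 0L) {
    if (is.null(labels)) {
      if (is.null(n)) n <- 0L
      labels <- if (n > 0L) paste0("v", seq_len(n)) else character()
    }
    return(new("DirectedNetwork", labels = as.character(labels),
               arcs = matrix(integer(), ncol = 2L,
                             dimnames = list(NULL, c("from", "to")))))
  }
  arcs <- as.matrix(arcs)
  if (ncol(arcs) != 2L)
    stop("arcs must have two columns (from, to)", call. = FALSE)
  if (is.character(arcs)) {
    if (is.null(labels))
      labels <- unique(as.vector(t(arcs)))
    else
      labels <- unique(c(as.character(labels), as.vector(t(arcs))))
    idx <- matrix(match(arcs, labels), ncol = 2L)
  } else {
    idx <- matrix(as.integer(arcs), ncol = 2L)
    if (is.null(labels)) {
      if (is.null(n)) n <- max(idx, 0L)
      labels <- paste0("v", seq_len(n))
    }
  }
  if (any(idx[, 1L] == idx[, 2L]))
    stop("self-arcs are excluded", call. = FALSE)
  idx <- unique(idx)
  dimnames(idx) <- list(NULL, c("from", "to"))
  new("DirectedNetwork", labels = as.character(labels), arcs = idx)
}

#' @rdname DirectedNetwork-class
#' @export
setMethod("numVertices", "DirectedNetwork", function(x) length(x@labels))

#' @rdname DirectedNetwork-class
#' @export
setMethod("vertexLabels", "DirectedNetwork", function(x) x@labels)

#' @rdname DirectedNetwork-class
#' @export
setMethod("arcs", "DirectedNetwork", function(x) x@arcs)

#' Count pure arcs and reciprocal dyads
#'
#' @param x A \code{DirectedNetwork}.
#' @return List with \code{pureArcs} (arcs whose opposite is absent),
#'   \code{reciprocalDyads} (unordered adjacent pairs with both arcs), and
#'   \code{orderedArcs} (total ordered arc count; equals
#'   \code{pureArcs + 2 * reciprocalDyads}).
#' @export
edgeTypeSummary <- function(x) {
  stopifnot(is(x, "DirectedNetwork"))
  a <- x@arcs
  if (nrow(a) == 0L)
    return(list(pureArcs = 0L, reciprocalDyads = 0L, orderedArcs = 0L))
  n <- numVertices(x)
  key <- (a[, 1L] - 1L) * n + a[, 2L]
  rkey <- (a[, 2L] - 1L) * n + a[, 1L]
  rec <- key %in% rkey
  list(pureArcs = sum(!rec), reciprocalDyads = sum(rec) %/% 2L,
       orderedArcs = nrow(a))
}

setMethod("show", "DirectedNetwork", function(object) {
  s <- edgeTypeSummary(object)
  cat("DirectedNetwork with", numVertices(object), "vertices and",
      s$orderedArcs, "arcs\n")
  cat("  pure arcs:", s$pureArcs,
      " reciprocal dyads:", s$reciprocalDyads, "\n")
})

## ---------------------------------------------------------------------------
## SignedWeightedNetwork
## ---------------------------------------------------------------------------

#' SignedWeightedNetwork: dense signed connectivity weights
#'
#' A square matrix of signed real weights with zero diagonal, e.g. the
#' signed path coefficients of a multivariate Granger-causality analysis:
#' entry \eqn{(i, j)} is the signed causal effect of region \eqn{i} on
#' region \eqn{j} (positive = excitatory, negative = inhibitory).
#'
#' @slot weights Numeric matrix with vertex labels as dimnames.
#'
#' @param x A \code{SignedWeightedNetwork}.
#' @aliases weightMatrix
#' @seealso \code{\link{splitBySign}}, \code{\link{pruneNetwork}}
#' @export
setClass("SignedWeightedNetwork", representation(weights = "matrix"))

setValidity("SignedWeightedNetwork", function(object) {
  w <- object@weights
  msg <- character()
  if (!is.numeric(w) || nrow(w) != ncol(w))
    msg <- c(msg, "weights must be a square numeric matrix")
  else {
    if (any(!is.finite(w)))
      msg <- c(msg, "weights must be finite")
    else if (any(diag(w) != 0))
      msg <- c(msg, "diagonal must be exactly zero")
    if (is.null(rownames(w)))
      msg <- c(msg, "weights must carry vertex labels as dimnames")
    else if (!identical(rownames(w), colnames(w)))
      msg <- c(msg, "row and column labels must agree")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SignedWeightedNetwork
#'
#' @param weights Square numeric matrix, zero diagonal.
#' @param labels Optional vertex labels; defaults to existing dimnames or
#'   \code{v1..vn}.
#' @return A \code{SignedWeightedNetwork}.
#' @export
SignedWeightedNetwork <- function(weights, labels = NULL) {
  weights <- as.matrix(weights)
  if (is.null(labels))
    labels <- rownames(weights)
  if (is.null(labels))
    labels <- paste0("v", seq_len(nrow(weights)))
  dimnames(weights) <- list(labels, labels)
  new("SignedWeightedNetwork", weights = weights)
}

#' @rdname SignedWeightedNetwork-class
#' @export
setMethod("weightMatrix", "SignedWeightedNetwork", function(x) x@weights)

#' @rdname SignedWeightedNetwork-class
#' @export
setMethod("numVertices", "SignedWeightedNetwork",
          function(x) nrow(x@weights))

#' @rdname SignedWeightedNetwork-class
#' @export
setMethod("vertexLabels", "SignedWeightedNetwork",
          function(x) rownames(x@weights))

setMethod("show", "SignedWeightedNetwork", function(object) {
  w <- object@weights
  nz <- sum(w != 0)
  cat("SignedWeightedNetwork with", nrow(w), "vertices;",
      nz, "nonzero weights (", sum(w > 0), "positive,",
      sum(w < 0), "negative )\n")
})

## ---------------------------------------------------------------------------
## SignatureMatrix
## ---------------------------------------------------------------------------

#' SignatureMatrix: per-vertex graphlet signature vectors
#'
#' The \eqn{N \times 16} table whose rows are the signature vectors of the
#' vertices of one network: out-, in-, and reciprocal-degree, the six wedge
#' isomorphism-class counts, and the seven triangle isomorphism-class
#' counts, in the fixed order of \code{\link{signatureClassNames}}.
#'
#' @slot counts Numeric matrix (integer-valued, nonnegative) with vertex
#'   labels as rownames and the 16 class names as colnames.
#'
#' @param x A \code{SignatureMatrix}.
#' @aliases signatureCounts
#' @seealso \code{\link{signatureMatrix}},
#'   \code{\link{graphletCorrelationMatrix}}
#' @export
setClass("SignatureMatrix", representation(counts = "matrix"))

setValidity("SignatureMatrix", function(object) {
  cnt <- object@counts
  msg <- character()
  if (ncol(cnt) != 16L || !identical(colnames(cnt), .SIGNATURE_NAMES))
    msg <- c(msg, "counts must have the 16 canonical signature columns")
  if (length(cnt) && (any(cnt < 0) || any(cnt != round(cnt))))
    msg <- c(msg, "counts must be nonnegative integers")
  if (is.null(rownames(cnt)))
    msg <- c(msg, "counts must carry vertex labels as rownames")
  if (length(msg)) msg else TRUE
})

#' @rdname SignatureMatrix-class
#' @export
setMethod("signatureCounts", "SignatureMatrix", function(x) x@counts)

#' @rdname SignatureMatrix-class
#' @export
setMethod("numVertices", "SignatureMatrix", function(x) nrow(x@counts))

#' @rdname SignatureMatrix-class
#' @export
setMethod("vertexLabels", "SignatureMatrix", function(x) rownames(x@counts))

setMethod("show", "SignatureMatrix", function(object) {
  cat("SignatureMatrix:", nrow(object@counts), "vertices x 16 classes\n")
  if (nrow(object@counts)) {
    k <- min(4L, nrow(object@counts))
    print(object@counts[seq_len(k), , drop = FALSE])
    if (nrow(object@counts) > k) cat("  ...\n")
  }
})

## ---------------------------------------------------------------------------
## GraphletCorrelationMatrix
## ---------------------------------------------------------------------------

#' GraphletCorrelationMatrix: Pearson correlations of signature columns
#'
#' The symmetric 16 x 16 matrix of Pearson correlation coefficients between
#' all pairs of signature-matrix columns of one network. Entries involving
#' a zero-variance column are undefined (\code{NA}) and flagged, never
#' silently imputed.
#'
#' @slot correlations Numeric 16 x 16 matrix; \code{NA} where undefined.
#' @slot defined Logical 16 x 16 matrix; \code{FALSE} where a zero-variance
#'   column makes Pearson's coefficient undefined.
#' @slot nVertices Number of vertices (rows) the matrix was computed from.
#'
#' @param x A \code{GraphletCorrelationMatrix}.
#' @aliases correlations definedEntries
#' @seealso \code{\link{graphletCorrelationMatrix}},
#'   \code{\link{significanceMask}}, \code{\link{consensus}}
#' @export
setClass("GraphletCorrelationMatrix",
         representation(correlations = "matrix", defined = "matrix",
                        nVertices = "integer"))

setValidity("GraphletCorrelationMatrix", function(object) {
  C <- object@correlations
  D <- object@defined
  msg <- character()
  if (!all(dim(C) == c(16L, 16L)) || !all(dim(D) == c(16L, 16L)))
    msg <- c(msg, "correlation and defined matrices must be 16 x 16")
  else {
    if (any(is.na(C) & D))
      msg <- c(msg, "defined entries must not be NA")
    ok <- D & !is.na(C)
    if (any(abs(C[ok]) > 1 + 1e-12))
      msg <- c(msg, "defined correlations must lie in [-1, 1]")
    if (!isTRUE(all.equal(C[ok], t(C)[t(ok) & ok])) && any(ok)) {
      Ct <- t(C)
      if (any(abs(C[ok & t(ok)] - Ct[ok & t(ok)]) > 1e-12))
        msg <- c(msg, "correlation matrix must be symmetric")
    }
  }
  if (length(msg)) msg else TRUE
})

#' @rdname GraphletCorrelationMatrix-class
#' @export
setMethod("correlations", "GraphletCorrelationMatrix",
          function(x) x@correlations)

#' @rdname GraphletCorrelationMatrix-class
#' @export
setMethod("definedEntries", "GraphletCorrelationMatrix",
          function(x) x@defined)

#' @rdname GraphletCorrelationMatrix-class
#' @export
setMethod("numVertices", "GraphletCorrelationMatrix",
          function(x) x@nVertices)

setMethod("show", "GraphletCorrelationMatrix", function(object) {
  nd <- sum(!object@defined[upper.tri(object@defined, diag = TRUE)])
  cat("GraphletCorrelationMatrix (16 x 16) from", object@nVertices,
      "vertices;", nd, "undefined entries (upper triangle)\n")
})

## ---------------------------------------------------------------------------
## ConsensusMatrix
## ---------------------------------------------------------------------------

#' ConsensusMatrix: cohort-level agreement on significant correlations
#'
#' For each of the 16 x 16 graphlet-correlation entries, the percentage of
#' subjects in a cohort whose entry is significantly positive
#' (correlation above the threshold) and the percentage with a
#' significantly negative entry (below minus the threshold).
#'
#' @slot positivePercent 16 x 16 matrix of percentages in [0, 100].
#' @slot negativePercent 16 x 16 matrix of percentages in [0, 100].
#' @slot nSubjects Number of subjects aggregated.
#' @slot threshold Correlation-magnitude significance threshold used.
#'
#' @seealso \code{\link{consensus}}, \code{\link{consensusMask}}
#' @export
setClass("ConsensusMatrix",
         representation(positivePercent = "matrix",
                        negativePercent = "matrix",
                        nSubjects = "integer", threshold = "numeric"))

setValidity("ConsensusMatrix", function(object) {
  p <- object@positivePercent
  q <- object@negativePercent
  msg <- character()
  if (!all(dim(p) == c(16L, 16L)) || !all(dim(q) == c(16L, 16L)))
    msg <- c(msg, "percentage matrices must be 16 x 16")
  else {
    if (any(p < 0 | p > 100) || any(q < 0 | q > 100))
      msg <- c(msg, "percentages must lie in [0, 100]")
    if (any(p + q > 100 + 1e-9))
      msg <- c(msg, "positive + negative percentage cannot exceed 100")
  }
  if (object@nSubjects < 1L)
    msg <- c(msg, "at least one subject required")
  if (length(msg)) msg else TRUE
})

#' @rdname ConsensusMatrix-class
#' @param x A \code{ConsensusMatrix}.
#' @param which \code{"positive"} or \code{"negative"}.
#' @return \code{consensusPercent}: the requested 16 x 16 percentage matrix.
#' @export
consensusPercent <- function(x, which = c("positive", "negative")) {
  stopifnot(is(x, "ConsensusMatrix"))
  which <- match.arg(which)
  if (which == "positive") x@positivePercent else x@negativePercent
}

#' @rdname ConsensusMatrix-class
#' @export
numSubjects <- function(x) {
  stopifnot(is(x, "ConsensusMatrix"))
  x@nSubjects
}

setMethod("show", "ConsensusMatrix", function(object) {
  cat("ConsensusMatrix over", object@nSubjects, "subjects",
      "(|r| >", object@threshold, ")\n")
  cat("  entries with positive consensus > 60%:",
      sum(object@positivePercent > 60), "\n")
  cat("  entries with negative consensus > 60%:",
      sum(object@negativePercent > 60), "\n")
})
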