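#' @include AllClasses.R
NULL

## Brute-force reference machinery for 2- and 3-node directed graphlets.
##
## A 3-node directed graph is encoded by the states of its three vertex
## pairs (1,2), (1,3), (2,3); each pair state is a 2-bit symbol:
##   0 = absent, 1 = forward (a -> b for a < b), 2 = backward, 3 = reciprocal.
## The code of the graph is the base-4 number s12*16 + s13*4 + s23; the
## canonical form is the minimum code over all 6 vertex permutations.

.pairState <- function(B, a, b) B[a, b] + 2L * B[b, a]

.codeFromMatrix <- function(M) {
  .pairState(M, 1L, 2L) * 16L + .pairState(M, 1L, 3L) * 4L +
    .pairState(M, 2L, 3L)
}

.matrixFromCode <- function(code) {
  s23 <- code %% 4L
  s13 <- (code %/% 4L) %% 4L
  s12 <- code %/% 16L
  M <- matrix(0L, 3L, 3L)
  put <- function(M, a, b, s) {
    if (s == 1L || s == 3L) M[a, b] <- 1L
    if (s == 2L || s == 3L) M[b, a] <- 1L
    M
  }
  M <- put(M, 1L, 2L, s12)
  M <- put(M, 1L, 3L, s13)
  put(M, 2L, 3L, s23)
}

.PERMS3 <- list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))

#' Canonical form of a 3-node directed graph
#'
#' The minimum, over all 6 vertex permutations, of the pair-state code of
#' the graph. Two 3-node digraphs are isomorphic iff their canonical forms
#' are equal (exhaustive minimization; no partial invariants).
#'
#' @param code Integer in 0..63: pair-state code (see source) of the graph,
#'   or a 3 x 3 binary adjacency matrix.
#' @return Integer canonical code.
#' @export
canonicalForm3 <- function(code) {
  if (is.matrix(code))
    code <- .codeFromMatrix(code)
  .canonTable()[code + 1L]
}

## Lookup table: canonical code for each of the 64 pair-state codes.
.canonTable <- function() {
  if (is.null(.cache$canon64)) {
    canon <- integer(64L)
    for (code in 0:63) {
      M <- .matrixFromCode(code)
      canon[code + 1L] <-
        min(vapply(.PERMS3, function(p) .codeFromMatrix(M[p, p]), integer(1L)))
    }
    .cache$canon64 <- canon
  }
  .cache$canon64
}

## Reference graphs fixing the name of each isomorphism class.
## Wedges are written with vertex 1 as the center (pair 2-3 absent).
.referenceCodes <- function() {
  if (is.null(.cache$refCodes)) {
    code3 <- function(s12, s13, s23) s12 * 16L + s13 * 4L + s23
    wedge <- c(
      W_out     = code3(1L, 1L, 0L),  # 1->2, 1->3
      W_in      = code3(2L, 2L, 0L),  # 2->1, 3->1
      W_path    = code3(1L, 2L, 0L),  # 1->2, 3->1
      W_out_rec = code3(1L, 3L, 0L),  # 1->2, 1<->3
      W_in_rec  = code3(2L, 3L, 0L),  # 2->1, 1<->3
      W_rec     = code3(3L, 3L, 0L))  # 1<->2, 1<->3
    triangle <- c(
      T_acyclic    = code3(1L, 1L, 1L),  # 1->2, 1->3, 2->3 (transitive)
      T_cycle      = code3(1L, 2L, 1L),  # 1->2, 2->3, 3->1
      T_out_rec    = code3(1L, 1L, 3L),  # 1->2, 1->3, 2<->3
      T_in_rec     = code3(2L, 2L, 3L),  # 2->1, 3->1, 2<->3
      T_cycle_rec  = code3(1L, 2L, 3L),  # 1->2, 3->1, 2<->3
      T_cycle_rec2 = code3(3L, 3L, 1L),  # 1<->2, 1<->3, 2->3
      T_rec        = code3(3L, 3L, 3L))
    canon <- .canonTable()
    .cache$refCodes <- list(wedge = canon[wedge + 1L],
                            triangle = canon[triangle + 1L])
    names(.cache$refCodes$wedge) <- names(wedge)
    names(.cache$refCodes$triangle) <- names(triangle)
  }
  .cache$refCodes
}

## Wedge class of an unordered pair of center-edge types.
.wedgeClassMap <- function() {
  if (is.null(.cache$wedgeMap)) {
    m <- matrix(NA_character_, 3L, 3L,
                dimnames = list(.EDGE_TYPES, .EDGE_TYPES))
    m["out", "out"] <- "W_out"
    m["in", "in"] <- "W_in"
    m["rec", "rec"] <- "W_rec"
    m["out", "in"] <- m["in", "out"] <- "W_path"
    m["out", "rec"] <- m["rec", "out"] <- "W_out_rec"
    m["in", "rec"] <- m["rec", "in"] <- "W_in_rec"
    .cache$wedgeMap <- m
  }
  .cache$wedgeMap
}

## Isomorphism class of each ordered (alpha, beta, gamma) triangle type.
## The tuple describes the triangle {i, h, j} with edges i-h typed alpha
## with respect to i, h-j typed beta with respect to j, and i-j typed gamma
## with respect to i; the map is computed by building each such triangle
## and canonicalizing it (never hard-coded).
.triangleTupleClassMap <- function() {
  if (is.null(.cache$tupleMap)) {
    ref <- .referenceCodes()$triangle
    m <- array(NA_character_, c(3L, 3L, 3L),
               dimnames = list(.EDGE_TYPES, .EDGE_TYPES, .EDGE_TYPES))
    for (a in .EDGE_TYPES) for (b in .EDGE_TYPES) for (g in .EDGE_TYPES) {
      M <- matrix(0L, 3L, 3L)  # vertices: 1 = i, 2 = h, 3 = j
      if (a %in% c("out", "rec")) M[1L, 2L] <- 1L
      if (a %in% c("in", "rec"))  M[2L, 1L] <- 1L
      if (b %in% c("out", "rec")) M[3L, 2L] <- 1L  # out wrt j: j -> h
      if (b %in% c("in", "rec"))  M[2L, 3L] <- 1L
      if (g %in% c("out", "rec")) M[1L, 3L] <- 1L
      if (g %in% c("in", "rec"))  M[3L, 1L] <- 1L
      cls <- names(ref)[match(canonicalForm3(M), ref)]
      m[a, b, g] <- cls
    }
    stopifnot(!anyNA(m))
    .cache$tupleMap <- m
  }
  .cache$tupleMap
}

## ---------------------------------------------------------------------------
## Exhaustive enumeration of small classes
## ---------------------------------------------------------------------------

#' Enumerate isomorphism classes of weakly connected k-node digraphs
#'
#' Assigns every combination of pair states (absent, forward, backward,
#' reciprocal) to the \eqn{k(k-1)/2} vertex pairs, keeps the weakly
#' connected graphs, and reduces by canonical form. For \code{k = 3} the
#' classes split by shape into wedges (exactly two adjacent pairs) and
#' triangles (all three pairs adjacent).
#'
#' @param k Graphlet size, 2 or 3.
#' @return A data frame with one row per isomorphism class: \code{shape}
#'   (\code{"edge"}, \code{"wedge"} or \code{"triangle"}), \code{class}
#'   (canonical name), \code{canonical} (integer code) and \code{nTypes}
#'   (number of labeled pair-state assignments in the class, fixing
#'   vertex 1; for \code{k = 3} wedges, assignments with vertex 1 as the
#'   center).
#' @export
#' @examples
#' enumerateConnectedDigraphs(3)  # 6 wedge + 7 triangle classes
enumerateConnectedDigraphs <- function(k) {
  if (!(k %in% c(2L, 3L)))
    stop("only k = 2 or k = 3 supported", call. = FALSE)
  if (k == 2L) {
    ## pair states 1, 2, 3; swap maps 1 <-> 2.
    states <- 1:3
    canon <- pmin(states, c(2L, 1L, 3L)[states])
    tab <- table(canon)
    return(data.frame(shape = "edge",
                      class = c("E_dir", "E_rec"),
                      canonical = as.integer(names(tab)),
                      nTypes = as.integer(tab)))
  }
  ref <- .referenceCodes()
  rows <- list()
  tally <- new.env(parent = emptyenv())
  for (code in 0:63) {
    s <- c(code %/% 16L, (code %/% 4L) %% 4L, code %% 4L)
    nAdj <- sum(s > 0L)
    if (nAdj < 2L) next  # not weakly connected on 3 vertices
    cc <- canonicalForm3(code)
    key <- as.character(cc)
    tally[[key]] <- c(if (!is.null(tally[[key]])) tally[[key]], code)
  }
  canonCodes <- as.integer(ls(tally))
  shape <- ifelse(canonCodes %in% ref$wedge, "wedge", "triangle")
  classNames <- character(length(canonCodes))
  classNames[shape == "wedge"] <-
    names(ref$wedge)[match(canonCodes[shape == "wedge"], ref$wedge)]
  classNames[shape == "triangle"] <-
    names(ref$triangle)[match(canonCodes[shape == "triangle"], ref$triangle)]
  stopifnot(!anyNA(classNames), all(nzchar(classNames)))
  ## nTypes: for wedges, count assignments in which vertex 1 is the center
  ## (the two adjacent pairs are (1,2) and (1,3)); for triangles, all
  ## assignments in the class contain vertex 1.
  nTypes <- vapply(as.character(canonCodes), function(key) {
    codes <- tally[[key]]
    s12 <- codes %/% 16L; s13 <- (codes %/% 4L) %% 4L; s23 <- codes %% 4L
    if (shape[match(as.integer(key), canonCodes)] == "wedge")
      sum(s12 > 0L & s13 > 0L & s23 == 0L)
    else
      length(codes)
  }, integer(1L))
  ord <- order(match(classNames, c(.WEDGE_CLASSES, .TRIANGLE_CLASSES)))
  out <- data.frame(shape = shape, class = classNames,
                    canonical = canonCodes, nTypes = as.integer(nTypes))
  out[ord, , drop = FALSE]
}

#' Census of ordered typed labels and reduced classes
#'
#' Counts the ordered type labels of the per-vertex quantities (3 degree
#' types, \eqn{3^2} ordered wedge types, \eqn{3^3} ordered triangle types,
#' 39 in total) and the isomorphism-class reduction (6 wedge classes, 7
#' triangle classes, 16-dimensional signature), the reduced classes by
#' exhaustive enumeration.
#'
#' @return Named list with components \code{degreeTypes},
#'   \code{wedgeTypes}, \code{triangleTypes}, \code{totalTyped},
#'   \code{wedgeClasses}, \code{triangleClasses}, \code{signatureLength}.
#' @export
enumerateTypedLabels <- function() {
  nT <- length(.EDGE_TYPES)
  enum <- enumerateConnectedDigraphs(3L)
  wc <- sum(enum$shape == "wedge")
  tc <- sum(enum$shape == "triangle")
  list(degreeTypes = nT,
       wedgeTypes = nT * nT,
       triangleTypes = nT * nT * nT,
       totalTyped = nT + nT * nT + nT * nT * nT,
       wedgeClasses = wc,
       triangleClasses = tc,
       signatureLength = nT + wc + tc)
}

## ---------------------------------------------------------------------------
## Brute-force signature
## ---------------------------------------------------------------------------

#' Brute-force signature vector by exhaustive 3-subset enumeration
#'
#' Reference implementation used as testing ground truth for the fast
#' matrix-product path: enumerates every unordered pair of other vertices,
#' classifies the induced subgraph on the triple by canonical form, and
#' tallies wedge classes only when \code{i} is the wedge center and
#' triangle classes whenever all three pairs are adjacent. Quadratic per
#' vertex, so restricted to small networks.
#'
#' @param x A \code{DirectedNetwork}.
#' @param i Vertex label or index.
#' @param cap Maximum number of vertices accepted (default 50).
#' @return Named numeric vector of the 16 signature coordinates.
#' @export
#' @seealso \code{\link{signatureVector}} for the production path.
oracleSignature <- function(x, i, cap = 50L) {
  stopifnot(is(x, "DirectedNetwork"))
  n <- numVertices(x)
  if (n > cap)
    stop("network too large for brute-force oracle (n = ", n,
         " > cap = ", cap, ")", call. = FALSE)
  idx <- .resolveVertex(vertexLabels(x), i)
  B <- adjacencyMatrix(x)
  sig <- .named(numeric(16L), .SIGNATURE_NAMES)
  others <- setdiff(seq_len(n), idx)
  typeOf <- function(a, b) {
    if (B[a, b] == 1L && B[b, a] == 1L) "rec"
    else if (B[a, b] == 1L) "out"
    else if (B[b, a] == 1L) "in"
    else NA_character_
  }
  for (j in others) {
    tp <- typeOf(idx, j)
    if (!is.na(tp)) sig[paste0("d_", tp)] <- sig[paste0("d_", tp)] + 1
  }
  wmap <- .wedgeClassMap()
  if (length(others) >= 2L) {
    for (a in seq_len(length(others) - 1L)) {
      for (b in (a + 1L):length(others)) {
        h <- others[a]; j <- others[b]
        adjIH <- B[idx, h] == 1L || B[h, idx] == 1L
        adjIJ <- B[idx, j] == 1L || B[j, idx] == 1L
        adjHJ <- B[h, j] == 1L || B[j, h] == 1L
        if (adjIH && adjIJ && adjHJ) {
          M <- B[c(idx, h, j), c(idx, h, j)]
          cls <- names(.referenceCodes()$triangle)[
            match(canonicalForm3(M), .referenceCodes()$triangle)]
          sig[cls] <- sig[cls] + 1
        } else if (adjIH && adjIJ) {
          cls <- wmap[typeOf(idx, h), typeOf(idx, j)]
          sig[cls] <- sig[cls] + 1
        }
      }
    }
  }
  sig
}

#' @rdname oracleSignature
#' @return \code{oracleSignatureMatrix}: a
#'   \code{\link{SignatureMatrix-class}} with one oracle row per vertex.
#' @export
oracleSignatureMatrix <- function(x, cap = 50L) {
  stopifnot(is(x, "DirectedNetwork"))
  counts <- t(vapply(seq_len(numVertices(x)),
                     function(i) oracleSignature(x, i, cap = cap),
                     numeric(16L)))
  dimnames(counts) <- list(vertexLabels(x), .SIGNATURE_NAMES)
  new("SignatureMatrix", counts = counts)
}
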