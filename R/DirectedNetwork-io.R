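#' @include AllClasses.R
NULL

## ---------------------------------------------------------------------------
## Reading
## ---------------------------------------------------------------------------

#' Read a directed network from an edge-list TSV
#'
#' One ordered pair per line, tab-separated: \code{source<TAB>target} with
#' an optional third \code{weight} column (preserved as an attribute for
#' downstream weighted preprocessing; binary analyses ignore it). Lines
#' starting with \code{#} are comments; a \code{# vertices:} comment, as
#' written by \code{\link{writeNetwork}}, fixes the vertex set so isolated
#' vertices survive a round trip. A header line \code{source target
#' [weight]} is accepted and skipped. Duplicate records are dropped; a pair
#' of opposite records \code{(i,j)}, \code{(j,i)} yields one reciprocal
#' edge. A self-arc record is an error.
#'
#' @param path Path to the TSV file.
#' @return A \code{\link{DirectedNetwork-class}} object. If a weight column
#'   is present it is attached as attribute \code{"weights"} (named by
#'   \code{from->to}).
#' @export
#' @seealso \code{\link{writeNetwork}}, \code{\link{readWeightMatrix}}
readEdgeList <- function(path) {
  lines <- readLines(path)
  labels <- character()
  comment <- startsWith(trimws(lines), "#")
  vline <- grep("^#\\s*vertices:", lines, value = TRUE)
  if (length(vline)) {
    v <- sub("^#\\s*vertices:\\s*", "", vline[1L])
    labels <- strsplit(v, "\t", fixed = TRUE)[[1L]]
    labels <- labels[nzchar(labels)]
  }
  keepLine <- !comment & nzchar(trimws(lines))
  body <- lines[keepLine]
  lineNo <- which(keepLine)
  ## optional header
  if (length(body) &&
      grepl("^source\\t(target|dst)", body[1L], ignore.case = TRUE)) {
    body <- body[-1L]
    lineNo <- lineNo[-1L]
  }
  from <- character(0); to <- character(0); w <- numeric(0)
  for (k in seq_along(body)) {
    fields <- strsplit(body[k], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 2L || length(fields) > 3L ||
        !nzchar(fields[1L]) || !nzchar(fields[2L]))
      stop("malformed edge record at line ", lineNo[k], ": ", body[k],
           call. = FALSE)
    if (fields[1L] == fields[2L])
      stop("self-arc at line ", lineNo[k], ": ", body[k], call. = FALSE)
    from <- c(from, fields[1L]); to <- c(to, fields[2L])
    if (length(fields) == 3L) {
      wk <- suppressWarnings(as.numeric(fields[3L]))
      if (is.na(wk))
        stop("malformed weight at line ", lineNo[k], ": ", body[k],
             call. = FALSE)
      w <- c(w, wk)
    } else w <- c(w, NA_real_)
  }
  g <- DirectedNetwork(cbind(from, to), labels = labels)
  if (any(!is.na(w))) {
    keep <- !duplicated(paste(from, to, sep = "\r"))
    wts <- w[keep]
    names(wts) <- paste0(from[keep], "->", to[keep])
    attr(g, "weights") <- wts
  }
  g
}

#' Read a dense adjacency or signed weight matrix from CSV
#'
#' Dense \eqn{n \times n} CSV with a header row of vertex labels and the
#' labels repeated in the first column; entry (row \eqn{i}, column
#' \eqn{j}) refers to the arc \eqn{i \to j}.
#'
#' @param path Path to the CSV file.
#' @return \code{readAdjacencyMatrix}: a \code{DirectedNetwork} (nonzero
#'   entries become arcs). \code{readWeightMatrix}: a
#'   \code{\link{SignedWeightedNetwork-class}} preserving signed weights.
#' @export
readAdjacencyMatrix <- function(path) {
  m <- .readSquareCSV(path)
  idx <- which(m != 0, arr.ind = TRUE)
  DirectedNetwork(idx, labels = rownames(m))
}

#' @rdname readAdjacencyMatrix
#' @export
readWeightMatrix <- function(path) {
  SignedWeightedNetwork(.readSquareCSV(path))
}

.readSquareCSV <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, row.names = 1L,
                        comment.char = "#")
  m <- as.matrix(df)
  if (nrow(m) != ncol(m))
    stop("adjacency CSV must be square", call. = FALSE)
  if (!identical(rownames(m), colnames(m)))
    stop("adjacency CSV row and column labels must agree", call. = FALSE)
  storage.mode(m) <- "double"
  m
}

## ---------------------------------------------------------------------------
## Writing
## ---------------------------------------------------------------------------

#' Write a directed network to file
#'
#' Edge-list format writes one ordered record per arc (both records of a
#' reciprocal edge), after a \code{# vertices:} comment carrying the full
#' label set and a \code{source<TAB>target} header. Adjacency format
#' writes the dense 0/1 CSV dialect of \code{\link{readAdjacencyMatrix}}.
#' Both round-trip losslessly, including isolated vertices.
#'
#' @param x A \code{DirectedNetwork}.
#' @param path Destination file path.
#' @param format \code{"edgelist"} (TSV) or \code{"adjacency"} (CSV).
#' @param header Optional extra comment lines (each prefixed with
#'   \code{# }) written before the data, e.g. provenance.
#' @return Invisibly, \code{path}.
#' @export
writeNetwork <- function(x, path, format = c("edgelist", "adjacency"),
                         header = NULL) {
  stopifnot(is(x, "DirectedNetwork"))
  format <- match.arg(format)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header))
    writeLines(paste("#", header), con)
  if (format == "edgelist") {
    writeLines(paste0("# vertices:\t",
                      paste(vertexLabels(x), collapse = "\t")), con)
    writeLines("source\ttarget", con)
    a <- arcs(x)
    if (nrow(a))
      writeLines(paste(vertexLabels(x)[a[, 1L]],
                       vertexLabels(x)[a[, 2L]], sep = "\t"), con)
  } else {
    m <- adjacencyMatrix(x)
    writeLines(paste(c("", colnames(m)), collapse = ","), con)
    for (i in seq_len(nrow(m)))
      writeLines(paste(c(rownames(m)[i], m[i, ]), collapse = ","), con)
  }
  invisible(path)
}

## ---------------------------------------------------------------------------
## Adjacency views
## ---------------------------------------------------------------------------

#' Binary adjacency matrix of a directed network
#'
#' @param x A \code{DirectedNetwork}.
#' @return Integer \eqn{n \times n} 0/1 matrix \eqn{A} with
#'   \eqn{a_{ij} = 1} iff the arc \eqn{i \to j} is present
#'   (\eqn{a_{ii} = 0}).
#' @export
adjacencyMatrix <- function(x) {
  stopifnot(is(x, "DirectedNetwork"))
  n <- numVertices(x)
  m <- matrix(0L, n, n, dimnames = list(vertexLabels(x), vertexLabels(x)))
  a <- arcs(x)
  if (nrow(a)) m[a] <- 1L
  m
}

#' Typed adjacency indicator matrices
#'
#' Splits the adjacency structure into the three edge-type indicators:
#' \eqn{A^{out}(i,j) = 1} iff \eqn{i \to j} is present and \eqn{j \to i}
#' absent; \eqn{A^{in}} is its transpose; \eqn{A^{rec}(i,j) = 1} iff both
#' arcs are present. The three supports are pairwise disjoint and their
#' union is the full adjacency.
#'
#' @param x A \code{DirectedNetwork}.
#' @return Named list of three integer 0/1 matrices: \code{out}, \code{in},
#'   \code{rec}.
#' @aliases typedAdjacency
#' @export
setMethod("typedAdjacency", "DirectedNetwork", function(x) {
  A <- adjacencyMatrix(x)
  At <- t(A)
  rec <- A * At
  list(out = A - rec, `in` = At - rec, rec = rec)
})

#' Typed neighbor sets of a vertex
#'
#' The out-neighbors (\eqn{i \to j} only), in-neighbors (\eqn{j \to i}
#' only) and reciprocal neighbors (\eqn{i \leftrightarrow j}) of vertex
#' \code{i}. The three sets are pairwise disjoint.
#'
#' @param x A \code{DirectedNetwork}.
#' @param i Vertex label or index.
#' @return Named list of character vectors \code{out}, \code{in},
#'   \code{rec} (vertex labels).
#' @export
neighborSets <- function(x, i) {
  stopifnot(is(x, "DirectedNetwork"))
  idx <- .resolveVertex(vertexLabels(x), i)
  ta <- typedAdjacency(x)
  lab <- vertexLabels(x)
  list(out = lab[ta$out[idx, ] == 1L],
       `in` = lab[ta$`in`[idx, ] == 1L],
       rec = lab[ta$rec[idx, ] == 1L])
}
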