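#' @include signatures.R
NULL

#' Graphlet correlation matrix
#'
#' Pearson correlation coefficients between all pairs of columns of a
#' signature matrix, collected in a symmetric 16 x 16 matrix — the
#' graphlet correlation matrix (GCM) of the network. Columns with zero
#' variance (a class absent from, or constant across, the whole network)
#' make Pearson's coefficient undefined; such entries are \code{NA} and
#' flagged via \code{\link{definedEntries}}, never silently imputed.
#'
#' @param x A \code{\link{SignatureMatrix-class}}, a plain numeric matrix
#'   with the 16 signature columns, or a \code{DirectedNetwork} (whose
#'   signature matrix is computed first).
#' @param ... Passed through between methods.
#' @return A \code{\link{GraphletCorrelationMatrix-class}}.
#' @aliases graphletCorrelationMatrix
#' @export
#' @examples
#' g <- randomDigraph(30, pArc = 0.3, pRec = 0.4, seed = 7)
#' gcm <- graphletCorrelationMatrix(signatureMatrix(g))
#' correlations(gcm)["d_out", "d_in"]
setMethod("graphletCorrelationMatrix", "SignatureMatrix",
          function(x, ...) {
  cnt <- signatureCounts(x)
  if (nrow(cnt) < 3L)
    stop("at least 3 vertices (rows) are required to correlate ",
         "signature columns", call. = FALSE)
  sds <- apply(cnt, 2L, stats::sd)
  def <- sds > 0
  C <- matrix(NA_real_, 16L, 16L,
              dimnames = list(.SIGNATURE_NAMES, .SIGNATURE_NAMES))
  if (any(def))
    C[def, def] <- stats::cor(cnt[, def, drop = FALSE])
  D <- outer(def, def, FUN = "&")
  dimnames(D) <- dimnames(C)
  new("GraphletCorrelationMatrix", correlations = C, defined = D,
      nVertices = nrow(cnt))
})

#' @rdname graphletCorrelationMatrix
#' @export
setMethod("graphletCorrelationMatrix", "DirectedNetwork",
          function(x, ...) graphletCorrelationMatrix(signatureMatrix(x)))

#' @rdname graphletCorrelationMatrix
#' @export
setMethod("graphletCorrelationMatrix", "matrix", function(x, ...) {
  stopifnot(ncol(x) == 16L)
  colnames(x) <- .SIGNATURE_NAMES
  if (is.null(rownames(x)))
    rownames(x) <- paste0("v", seq_len(nrow(x)))
  graphletCorrelationMatrix(new("SignatureMatrix", counts = x))
})

#' Significance mask of a graphlet correlation matrix
#'
#' Ternary mask of significant correlations: \code{+1} where the
#' correlation is strictly greater than the threshold, \code{-1} where
#' strictly less than minus the threshold, \code{0} otherwise. The
#' inequalities are strict (a coefficient exactly at the threshold is not
#' significant) and undefined entries map to 0.
#'
#' @param x A \code{GraphletCorrelationMatrix}.
#' @param threshold Correlation-magnitude threshold in (0, 1]; default
#'   0.7.
#' @return Integer 16 x 16 matrix with entries in \code{-1, 0, +1}.
#' @aliases significanceMask
#' @export
setMethod("significanceMask", "GraphletCorrelationMatrix",
          function(x, threshold = 0.7) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1)
    stop("threshold must be a single number in (0, 1]", call. = FALSE)
  C <- correlations(x)
  m <- matrix(0L, 16L, 16L, dimnames = dimnames(C))
  m[!is.na(C) & C > threshold] <- 1L
  m[!is.na(C) & C < -threshold] <- -1L
  m
})

#' Structural similarity of two vertices
#'
#' Pearson correlation of the two vertices' signature vectors. Undefined
#' (returned as \code{NA}) when either signature is constant.
#'
#' @param x A \code{SignatureMatrix}.
#' @param i,j Vertex labels or indices.
#' @return A single correlation in [-1, 1], or \code{NA} if undefined.
#' @export
vertexSimilarity <- function(x, i, j) {
  stopifnot(is(x, "SignatureMatrix"))
  cnt <- signatureCounts(x)
  ri <- cnt[.resolveVertex(rownames(cnt), i), ]
  rj <- cnt[.resolveVertex(rownames(cnt), j), ]
  if (stats::sd(ri) == 0 || stats::sd(rj) == 0)
    return(NA_real_)
  stats::cor(ri, rj)
}

#' Ward clustering of vertices by signature
#'
#' Agglomerative hierarchical clustering (Ward linkage, \code{ward.D2})
#' of the vertices on Euclidean distances between their signature rows,
#' \code{log1p}-transformed by default because raw graphlet counts are
#' heavy-tailed and would otherwise be dominated by the degree block.
#' Returns the leaf ordering used for heat-map display and, when \code{k}
#' is given, the flat cluster labels.
#'
#' @param x A \code{SignatureMatrix}.
#' @param k Optional number of flat clusters to cut the tree into.
#' @param scale \code{"log1p"} (default) or \code{"raw"} counts for the
#'   distance computation.
#' @return List with \code{hclust} (the tree), \code{order} (leaf order,
#'   vertex labels) and \code{clusters} (named integer labels, or
#'   \code{NULL} when \code{k} is missing).
#' @export
clusterVertices <- function(x, k = NULL, scale = c("log1p", "raw")) {
  stopifnot(is(x, "SignatureMatrix"))
  scale <- match.arg(scale)
  cnt <- signatureCounts(x)
  if (scale == "log1p") cnt <- log1p(cnt)
  hc <- stats::hclust(stats::dist(cnt), method = "ward.D2")
  clusters <- NULL
  if (!is.null(k)) {
    clusters <- stats::cutree(hc, k = k)
    names(clusters) <- rownames(cnt)
  }
  list(hclust = hc, order = rownames(cnt)[hc$order], clusters = clusters)
}

#' Write / read a graphlet correlation matrix as CSV
#'
#' 16 x 16 CSV with class-name headers; undefined entries are serialized
#' as empty cells and restored as \code{NA}.
#'
#' @param x A \code{GraphletCorrelationMatrix}.
#' @param path File path.
#' @param header Optional comment lines written first (prefixed
#'   \code{# }).
#' @return \code{writeGCM}: invisibly, \code{path}; \code{readGCM}: a
#'   \code{GraphletCorrelationMatrix}.
#' @export
writeGCM <- function(x, path, header = NULL) {
  stopifnot(is(x, "GraphletCorrelationMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header))
    writeLines(paste("#", header), con)
  C <- correlations(x)
  writeLines(paste(c("", colnames(C)), collapse = ","), con)
  for (i in seq_len(nrow(C))) {
    vals <- ifelse(is.na(C[i, ]), "", format(C[i, ], digits = 15L,
                                             trim = TRUE, scientific = FALSE))
    writeLines(paste(c(rownames(C)[i], vals), collapse = ","), con)
  }
  invisible(path)
}

#' @rdname writeGCM
#' @export
readGCM <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, row.names = 1L,
                        comment.char = "#")
  C <- as.matrix(df)
  storage.mode(C) <- "double"
  if (!all(dim(C) == c(16L, 16L)))
    stop("not a 16 x 16 GCM CSV", call. = FALSE)
  dimnames(C) <- list(.SIGNATURE_NAMES, .SIGNATURE_NAMES)
  new("GraphletCorrelationMatrix", correlations = C, defined = !is.na(C),
      nVertices = NA_integer_)
}
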