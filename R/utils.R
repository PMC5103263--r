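## Internal constants and helpers shared across the package.

## Edge types with respect to a reference vertex i:
##   "out": i -> j only;  "in": j -> i only;  "rec": i <-> j.
.EDGE_TYPES <- c("out", "in", "rec")

.WEDGE_CLASSES <- c("W_out", "W_in", "W_path", "W_out_rec", "W_in_rec", "W_rec")

.TRIANGLE_CLASSES <- c("T_acyclic", "T_cycle", "T_out_rec", "T_in_rec",
                       "T_cycle_rec", "T_cycle_rec2", "T_rec")

.SIGNATURE_NAMES <- c("d_out", "d_in", "d_rec",
                      .WEDGE_CLASSES, .TRIANGLE_CLASSES)

#' Canonical signature coordinate names
#'
#' The fixed order of the 16 signature coordinates: the three 2-node degrees
#' (out, in, reciprocal), the six wedge isomorphism classes, and the seven
#' triangle isomorphism classes.
#'
#' @return Character vector of length 16.
#' @export
#' @examples
#' signatureClassNames()
signatureClassNames <- function() .SIGNATURE_NAMES

## Memoised enumeration tables (canonical forms, class maps), built on first
## use by exhaustive enumeration -- see oracle.R.
.cache <- new.env(parent = emptyenv())

## Resolve a vertex given as label or index to an integer index.
.resolveVertex <- function(labels, i) {
  if (is.character(i)) {
    idx <- match(i, labels)
    if (is.na(idx))
      stop("unknown vertex label: ", i, call. = FALSE)
    return(idx)
  }
  i <- as.integer(i)
  if (is.na(i) || i < 1L || i > length(labels))
    stop("vertex index out of range: ", i, call. = FALSE)
  i
}

## Drop-dimension-safe named vector constructor.
.named <- function(x, nms) {
  names(x) <- nms
  x
}
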