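#' @include utils.R
NULL

#' @rdname DirectedNetwork-class
#' @export
setGeneric("numVertices", function(x) standardGeneric("numVertices"))

#' @rdname DirectedNetwork-class
#' @export
setGeneric("vertexLabels", function(x) standardGeneric("vertexLabels"))

#' @rdname DirectedNetwork-class
#' @export
setGeneric("arcs", function(x) standardGeneric("arcs"))

#' @rdname typedAdjacency
#' @export
setGeneric("typedAdjacency", function(x) standardGeneric("typedAdjacency"))

#' @rdname signatureMatrix
#' @export
setGeneric("signatureMatrix", function(x, ...) standardGeneric("signatureMatrix"))

#' @rdname SignatureMatrix-class
#' @export
setGeneric("signatureCounts", function(x) standardGeneric("signatureCounts"))

#' @rdname graphletCorrelationMatrix
#' @export
setGeneric("graphletCorrelationMatrix",
           function(x, ...) standardGeneric("graphletCorrelationMatrix"))

#' @rdname GraphletCorrelationMatrix-class
#' @export
setGeneric("correlations", function(x) standardGeneric("correlations"))

#' @rdname GraphletCorrelationMatrix-class
#' @export
setGeneric("definedEntries", function(x) standardGeneric("definedEntries"))

#' @rdname significanceMask
#' @export
setGeneric("significanceMask",
           function(x, threshold = 0.7) standardGeneric("significanceMask"))

#' @rdname SignedWeightedNetwork-class
#' @export
setGeneric("weightMatrix", function(x) standardGeneric("weightMatrix"))
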