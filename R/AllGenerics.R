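#' @import methods
NULL

#' @export
setGeneric("reference", function(x) standardGeneric("reference"))

#' @export
setGeneric("strand", function(x, ...) standardGeneric("strand"))

#' @export
setGeneric("coordinate", function(x) standardGeneric("coordinate"))

#' @export
setGeneric("beginPosition", function(x) standardGeneric("beginPosition"))

#' @export
setGeneric("endPosition", function(x) standardGeneric("endPosition"))

#' @export
setGeneric("biologicalStart", function(x) standardGeneric("biologicalStart"))

#' @export
setGeneric("biologicalEnd", function(x) standardGeneric("biologicalEnd"))

#' @export
setGeneric("normalizedArcs", function(x, ref) standardGeneric("normalizedArcs"))

#' @export
setGeneric("regionLength", function(x, ref) standardGeneric("regionLength"))

#' @export
setGeneric("fuzzyEnvelope", function(x, ref = NULL)
  standardGeneric("fuzzyEnvelope"))

#' @export
setGeneric("positionKey", function(x) standardGeneric("positionKey"))
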