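## Coordinate arithmetic over the location model.
##
## "Arcs" are the numerically normalized (min <= max, 1-based inclusive)
## intervals a region covers on its reference.  A non-wrapping region yields
## one arc; an origin-spanning region on a circular reference yields two
## ([begin, L] and [1, end]).  Arcs are the common currency for overlap
## queries and for export to start<=end formats (GFF3, BED).
##
## Wrap detection is strand-aware: a region wraps when its numeric endpoint
## order contradicts the normal orientation for its strand on a circular
## reference.  Forward or untyped regions normally have begin <= end, so
## begin > end signals a wrap; reverse-strand regions normally have
## begin >= end (begin is the biological start), so begin < end signals a
## wrap.  On a linear reference nothing wraps.

#' @describeIn Region-class the biological start position (begin; the 5'-most
#'   base in transcription order — numerically the larger coordinate for
#'   reverse-strand features)
#' @export
setMethod("biologicalStart", "Region", function(x) x@begin)

#' @describeIn Region-class the biological end position
#' @export
setMethod("biologicalEnd", "Region", function(x) x@end)

#' @describeIn Position-class a position is its own start
#' @export
setMethod("biologicalStart", "Position", function(x) x)

#' @describeIn Position-class a position is its own end
#' @export
setMethod("biologicalEnd", "Position", function(x) x)

## outer-bound coordinate of a position, for arc computation
envelopeOf <- function(p, ref = NULL) {
  fuzzyEnvelope(p, ref)
}

fuzzyEnvelopeSafe <- function(p, ref = NULL) {
  tryCatch(fuzzyEnvelope(p, ref), faldorError = function(e) c(NA, NA))
}

#' Outer-bound envelope of a position
#'
#' The smallest inclusive coordinate interval guaranteed to contain the true
#' position.  Exact positions give a width-1 interval; in-range positions
#' give their bounds; one-of positions the min/max over candidates;
#' in-between positions the two flanking bases.  An unbounded in-range side
#' defaults to 1 (low side) or to the reference length (high side) when the
#' reference length is known.
#'
#' @param x a \code{Position}
#' @param ref optional \code{ReferenceSequence} supplying a length for
#'   unbounded high sides
#' @return integer(2): (min, max)
#' @examples
#' fuzzyEnvelope(OneOfPosition(list(1888, 1901), "x"))  # 1888 1901
#' @export
setMethod("fuzzyEnvelope", "ExactPosition", function(x, ref = NULL) {
  c(x@coordinate, x@coordinate)
})

#' @rdname fuzzyEnvelope-ExactPosition-method
#' @export
setMethod("fuzzyEnvelope", "InRangePosition", function(x, ref = NULL) {
  lo <- if (!is.null(x@lowBound)) fuzzyEnvelope(x@lowBound, ref)[1] else 1L
  hi <- if (!is.null(x@highBound)) {
    fuzzyEnvelope(x@highBound, ref)[2]
  } else if (!is.null(ref) && !is.na(ref@length)) {
    ref@length
  } else {
    stopFaldor("UnboundedEnvelope",
      "unbounded high side and no reference length to bound it")
  }
  c(as.integer(lo), as.integer(hi))
})

#' @rdname fuzzyEnvelope-ExactPosition-method
#' @export
setMethod("fuzzyEnvelope", "OneOfPosition", function(x, ref = NULL) {
  envs <- vapply(x@options, function(o) fuzzyEnvelope(o, ref), integer(2))
  c(min(envs[1, ]), max(envs[2, ]))
})

#' @rdname fuzzyEnvelope-ExactPosition-method
#' @export
setMethod("fuzzyEnvelope", "InBetweenPosition", function(x, ref = NULL) {
  a <- fuzzyEnvelope(x@after, ref)
  b <- fuzzyEnvelope(x@before, ref)
  c(min(a[1], b[1]), max(a[2], b[2]))
})

## does this region wrap the origin of a circular reference?
regionWraps <- function(x, ref, bmin, emin) {
  if (is.null(ref) || !identical(ref@topology, "circular")) return(FALSE)
  s <- x@begin@strand
  if (!is.na(s) && s == "reverse") bmin < emin else bmin > emin
}

#' Normalized coordinate arcs of a region
#'
#' @param x a \code{Region} (endpoints exact or fuzzy; fuzzy endpoints are
#'   resolved to their outer envelope)
#' @param ref the \code{ReferenceSequence} the region lies on; \code{NULL}
#'   is treated as an anonymous linear reference
#' @return a data.frame with integer columns \code{start} and \code{end}
#'   (1-based inclusive, start <= end), one row per arc: one row for
#'   non-wrapping regions, two for origin-spanning regions on a circular
#'   reference
#' @examples
#' r <- Region(ExactPosition(6006, "J02448"), ExactPosition(831, "J02448"))
#' normalizedArcs(r, ReferenceSequence("J02448", 6407, "circular"))
#' @export
setMethod("normalizedArcs", "Region", function(x, ref) {
  if (missing(ref)) ref <- NULL
  if (!identical(x@begin@reference, x@end@reference))
    stopFaldor("MultiReferenceRegion",
      sprintf("region endpoints are on different references (%s vs %s)",
              x@begin@reference, x@end@reference))
  benv <- fuzzyEnvelope(x@begin, ref)
  eenv <- fuzzyEnvelope(x@end, ref)
  b <- benv[1]; e <- eenv[1]
  lo <- min(benv[1], eenv[1])
  hi <- max(benv[2], eenv[2])
  ## wrap test uses the representative (outermost toward the feature body)
  ## coordinate of each endpoint
  bc <- if (!is.na(x@begin@strand) && x@begin@strand == "reverse")
    benv[2] else benv[1]
  ec <- if (!is.na(x@end@strand) && x@end@strand == "reverse")
    eenv[1] else eenv[2]
  if (regionWraps(x, ref, bc, ec)) {
    if (is.na(ref@length))
      stopFaldor("MissingLength",
        "origin-spanning region on a circular reference of unknown length")
    s <- x@begin@strand
    if (!is.na(s) && s == "reverse") {
      ## reverse wrap: biological start is numerically low, runs backwards
      ## through the origin; covered arcs are [1, begin] and [end, L]
      data.frame(start = c(1L, as.integer(eenv[1])),
                 end = c(as.integer(benv[2]), ref@length))
    } else {
      data.frame(start = c(as.integer(benv[1]), 1L),
                 end = c(ref@length, as.integer(eenv[2])))
    }
  } else {
    data.frame(start = as.integer(lo), end = as.integer(hi))
  }
})

#' @rdname normalizedArcs-Region-method
#' @export
setMethod("normalizedArcs", "Position", function(x, ref) {
  if (missing(ref)) ref <- NULL
  env <- fuzzyEnvelope(x, ref)
  data.frame(start = as.integer(env[1]), end = as.integer(env[2]))
})

#' @rdname normalizedArcs-Region-method
#' @export
setMethod("normalizedArcs", "RegionCollection", function(x, ref) {
  if (missing(ref)) ref <- NULL
  if (length(x@members) == 0L)
    return(data.frame(start = integer(), end = integer()))
  do.call(rbind, lapply(x@members, normalizedArcs, ref = ref))
})

#' Inclusive length of a region in bases
#'
#' Uses 1-based inclusive counting: a region with begin = end has length 1.
#' Origin-spanning regions on a circular reference count both arcs:
#' (L - begin + 1) + end.
#'
#' @param x a \code{Region}, \code{Position} or \code{RegionCollection}
#' @param ref the \code{ReferenceSequence} (needed for circular wrap)
#' @return integer(1)
#' @examples
#' chey <- parseInsdc("complement(1965072..1965461)", "NC_000913.2")
#' regionLength(chey)  # 390
#' @export
setMethod("regionLength", "Region", function(x, ref) {
  if (missing(ref)) ref <- NULL
  arcs <- normalizedArcs(x, ref)
  as.integer(sum(arcs$end - arcs$start + 1L))
})

#' @rdname regionLength-Region-method
#' @export
setMethod("regionLength", "Position", function(x, ref) {
  if (missing(ref)) ref <- NULL
  arcs <- normalizedArcs(x, ref)
  as.integer(sum(arcs$end - arcs$start + 1L))
})

#' @rdname regionLength-Region-method
#' @export
setMethod("regionLength", "RegionCollection", function(x, ref) {
  if (missing(ref)) ref <- NULL
  arcs <- normalizedArcs(x, ref)
  as.integer(sum(arcs$end - arcs$start + 1L))
})
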