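## S4 class hierarchy for the FALDO location model.
##
## The central design points, mirrored from the ontology:
##   * strand and reference sequence are properties of a *position*, never of a
##     region, so a region's two endpoints may legitimately sit on different
##     strands (restriction-enzyme sticky ends) or different reference
##     sequences (trans-spliced or multi-contig features);
##   * coordinates are 1-based, inclusive, and always counted from the 5' end
##     of the forward strand, even for reverse-strand features;
##   * a region's begin is the *biological* start, so begin may be numerically
##     greater than end (reverse strand, or origin wrap on a circular
##     replicon);
##   * "strand unknown" is expressed by the *absence* of a strand claim
##     (NA), never by a sentinel value, so that merging datasets can never
##     produce a position typed both forward-stranded and unknown-stranded.

STRAND_VALUES <- c("forward", "reverse", "both")

validStrand <- function(strand) {
  if (length(strand) != 1L)
    return("strand must be a single value (NA for no strand claim)")
  if (!is.na(strand) && !strand %in% STRAND_VALUES)
    return(sprintf("strand must be NA or one of: %s",
                   paste(STRAND_VALUES, collapse = ", ")))
  NULL
}

#' Virtual superclass of all FALDO positions
#'
#' A position on a biological sequence.  Every position names the reference
#' sequence it is measured on and may carry an optional strand claim
#' (\code{"forward"}, \code{"reverse"}, \code{"both"}, or \code{NA} meaning
#' no claim is made).
#'
#' @slot reference character(1); identifier (IRI or accession) of the
#'   reference sequence the coordinate is counted on.  May be \code{""} only
#'   transiently (e.g. a bound inside another position that inherits its
#'   parent's reference).
#' @slot strand character(1); \code{"forward"}, \code{"reverse"},
#'   \code{"both"}, or \code{NA_character_} for no strand claim.
#' @aliases Position-class
#' @exportClass Position
setClass("Position", representation("VIRTUAL",
  reference = "character",
  strand = "character"
))

setValidity("Position", function(object) {
  msgs <- character()
  if (length(object@reference) != 1L)
    msgs <- c(msgs, "reference must be a single string")
  m <- validStrand(object@strand)
  if (!is.null(m)) msgs <- c(msgs, m)
  if (length(msgs)) msgs else TRUE
})

setClassUnion("PositionOrNULL", "NULL")

#' Exactly known position
#'
#' @slot coordinate integer(1); 1-based offset from the 5' end of the forward
#'   strand.  Must be >= 1.
#' @aliases ExactPosition-class
#' @exportClass ExactPosition
setClass("ExactPosition", contains = "Position",
  representation(coordinate = "integer"))

setValidity("ExactPosition", function(object) {
  msgs <- character()
  if (length(object@coordinate) != 1L || is.na(object@coordinate))
    msgs <- c(msgs, "coordinate must be a single non-missing integer")
  else if (object@coordinate < 1L)
    msgs <- c(msgs, "coordinate must be >= 1 (1-based counting)")
  if (!nzchar(object@reference))
    msgs <- c(msgs, "an ExactPosition must name its reference sequence")
  if (length(msgs)) msgs else TRUE
})

#' @aliases NTerminalPosition-class
#' @exportClass NTerminalPosition
#' @rdname ExactPosition-class
setClass("NTerminalPosition", contains = "ExactPosition")

setValidity("NTerminalPosition", function(object) {
  if (length(object@coordinate) == 1L && !is.na(object@coordinate) &&
      object@coordinate != 1L)
    "an N-terminal position must have coordinate 1"
  else TRUE
})

#' @aliases CTerminalPosition-class
#' @exportClass CTerminalPosition
#' @rdname ExactPosition-class
setClass("CTerminalPosition", contains = "ExactPosition")

#' Virtual superclass of the fuzzy positions
#'
#' @aliases FuzzyPosition-class
#' @exportClass FuzzyPosition
setClass("FuzzyPosition", contains = "Position", representation("VIRTUAL"))

setClassUnion("PositionOrNULL", members = c("Position", "NULL"))

#' Position known only to lie within a range
#'
#' At least one bound must be present; an absent bound means the position may
#' extend arbitrarily far on that side (INSDC \code{<n} / \code{>n}).
#'
#' @slot lowBound a \code{Position} or \code{NULL}.
#' @slot highBound a \code{Position} or \code{NULL}.
#' @aliases InRangePosition-class
#' @exportClass InRangePosition
setClass("InRangePosition", contains = "FuzzyPosition",
  representation(lowBound = "PositionOrNULL", highBound = "PositionOrNULL"))

setValidity("InRangePosition", function(object) {
  msgs <- character()
  if (is.null(object@lowBound) && is.null(object@highBound))
    msgs <- c(msgs, "at least one of lowBound/highBound must be present")
  if (is(object@lowBound, "ExactPosition") &&
      is(object@highBound, "ExactPosition") &&
      object@lowBound@coordinate > object@highBound@coordinate)
    msgs <- c(msgs, "lowBound coordinate must be <= highBound coordinate")
  if (!nzchar(object@reference))
    msgs <- c(msgs, "an InRangePosition must name its reference sequence")
  if (length(msgs)) msgs else TRUE
})

#' Position known to be one of several candidates
#'
#' @slot options list of at least two distinct \code{Position} objects.
#' @aliases OneOfPosition-class
#' @exportClass OneOfPosition
setClass("OneOfPosition", contains = "FuzzyPosition",
  representation(options = "list"))

setValidity("OneOfPosition", function(object) {
  msgs <- character()
  if (!all(vapply(object@options, is, logical(1), class2 = "Position")))
    msgs <- c(msgs, "all options must be Position objects")
  else {
    keys <- vapply(object@options, positionKey, character(1))
    if (length(unique(keys)) < 2L)
      msgs <- c(msgs, "options must contain at least 2 distinct positions")
  }
  if (!nzchar(object@reference))
    msgs <- c(msgs, "a OneOfPosition must name its reference sequence")
  if (length(msgs)) msgs else TRUE
})

#' Position between two adjacent bases
#'
#' Describes a point that falls between two bases rather than on one, e.g. a
#' restriction-enzyme cut site or an INSDC \code{n^m} location.  On a linear
#' reference with exact neighbours, \code{before} must be the base directly
#' after \code{after} (\code{before = after + 1}).
#'
#' @slot after the \code{Position} immediately 5' of the point.
#' @slot before the \code{Position} immediately 3' of the point.
#' @aliases InBetweenPosition-class
#' @exportClass InBetweenPosition
setClass("InBetweenPosition", contains = "FuzzyPosition",
  representation(after = "Position", before = "Position"))

setValidity("InBetweenPosition", function(object) {
  msgs <- character()
  a <- object@after; b <- object@before
  if (is(a, "ExactPosition") && is(b, "ExactPosition") &&
      identical(a@reference, b@reference)) {
    ## circular adjacency (length -> 1) cannot be checked without topology
    ## metadata, so only the linear rule is enforced structurally
    if (b@coordinate != a@coordinate + 1L && b@coordinate != 1L)
      msgs <- c(msgs,
        "before must be the base directly after 'after' (before = after + 1)")
  }
  if (length(msgs)) msgs else TRUE
})

#' Region: a biologically oriented pair of positions
#'
#' \code{begin} is the biological start (5'-most in transcription order) and
#' may be numerically greater than \code{end} for reverse-strand or
#' origin-spanning features.  Endpoints carry their own strand and reference,
#' which may differ between the two.
#'
#' @slot begin the begin \code{Position} (biological start).
#' @slot end the end \code{Position} (biological end).
#' @aliases Region-class
#' @exportClass Region
setClass("Region", representation(begin = "Position", end = "Position"))

#' Grouping of biologically related regions
#'
#' Mirrors the ontology's collection classes used for INSDC compound
#' locations: \code{"list"} (from \code{join(...)}, order meaningful),
#' \code{"bag"} (from \code{order(...)}, order unknown) and the generic
#' \code{"collection"}.
#'
#' @slot kind character(1); \code{"list"}, \code{"bag"} or
#'   \code{"collection"}.
#' @slot members list of \code{Region} objects.
#' @aliases RegionCollection-class
#' @exportClass RegionCollection
setClass("RegionCollection",
  representation(kind = "character", members = "list"))

setValidity("RegionCollection", function(object) {
  msgs <- character()
  if (length(object@kind) != 1L ||
      !object@kind %in% c("list", "bag", "collection"))
    msgs <- c(msgs, "kind must be one of 'list', 'bag', 'collection'")
  if (!all(vapply(object@members, is, logical(1), class2 = "Region")))
    msgs <- c(msgs, "all members must be Region objects")
  if (length(msgs)) msgs else TRUE
})

setClassUnion("Location", members = c("Position", "Region", "RegionCollection"))

#' A sequence feature and where it is found
#'
#' Separates the feature (its identifier, type term and attributes) from its
#' location(s).  A feature may carry several locations, e.g. coordinates on
#' two genome assemblies or both gene-relative and chromosome-relative
#' positions.
#'
#' @slot featureId character(1) identifier (IRI or plain string).
#' @slot featureType character(1) type term (e.g. a Sequence Ontology name).
#' @slot locations non-empty list of \code{Position}, \code{Region} or
#'   \code{RegionCollection} objects.
#' @slot attributes named list of additional key/value attributes.
#' @aliases FeatureRecord-class
#' @exportClass FeatureRecord
setClass("FeatureRecord", representation(
  featureId = "character",
  featureType = "character",
  locations = "list",
  attributes = "list"
))

setValidity("FeatureRecord", function(object) {
  msgs <- character()
  if (length(object@featureId) != 1L || !nzchar(object@featureId))
    msgs <- c(msgs, "featureId must be a single non-empty string")
  if (length(object@locations) < 1L)
    msgs <- c(msgs, "a feature must have at least one location")
  ok <- vapply(object@locations, function(l)
    is(l, "Position") || is(l, "Region") || is(l, "RegionCollection"),
    logical(1))
  if (!all(ok))
    msgs <- c(msgs, "locations must be Position/Region/RegionCollection")
  if (length(object@attributes) &&
      (is.null(names(object@attributes)) || any(!nzchar(names(object@attributes)))))
    msgs <- c(msgs, "attributes must be a named list")
  if (length(msgs)) msgs else TRUE
})

#' Reference sequence metadata
#'
#' @slot id character(1) identifier.
#' @slot length integer(1); sequence length, \code{NA} if unknown.
#' @slot topology character(1); \code{"linear"} or \code{"circular"}.
#'   Circular wrap arithmetic requires a known length.
#' @aliases ReferenceSequence-class
#' @exportClass ReferenceSequence
setClass("ReferenceSequence", representation(
  id = "character", length = "integer", topology = "character"))

setValidity("ReferenceSequence", function(object) {
  msgs <- character()
  if (length(object@id) != 1L || !nzchar(object@id))
    msgs <- c(msgs, "id must be a single non-empty string")
  if (length(object@topology) != 1L ||
      !object@topology %in% c("linear", "circular"))
    msgs <- c(msgs, "topology must be 'linear' or 'circular'")
  if (length(object@length) != 1L)
    msgs <- c(msgs, "length must be a single integer (NA if unknown)")
  else if (!is.na(object@length) && object@length < 1L)
    msgs <- c(msgs, "length must be positive")
  if (length(msgs)) msgs else TRUE
})

## ---- constructors ---------------------------------------------------------

asStrand <- function(strand) {
  if (is.null(strand) || length(strand) == 0L) return(NA_character_)
  strand <- as.character(strand)
  m <- validStrand(strand)
  if (!is.null(m)) stopFaldor("InvalidStrand", m)
  strand
}

#' Create an exact position
#'
#' @param coordinate 1-based coordinate (>= 1).
#' @param reference reference sequence identifier.
#' @param strand \code{"forward"}, \code{"reverse"}, \code{"both"} or
#'   \code{NA} (default) for no strand claim.
#' @return An \code{ExactPosition}.
#' @examples
#' ExactPosition(1965461, "NC_000913.2", strand = "reverse")
#' @export
ExactPosition <- function(coordinate, reference, strand = NA) {
  if (length(coordinate) != 1L || is.na(coordinate) || coordinate < 1 ||
      coordinate != as.integer(coordinate))
    stopFaldor("InvalidCoordinate",
               sprintf("invalid coordinate: %s", deparse(coordinate)))
  new("ExactPosition", coordinate = as.integer(coordinate),
      reference = as.character(reference), strand = asStrand(strand))
}

#' @param kind \code{"N"} or \code{"C"} terminal.
#' @rdname ExactPosition
#' @export
TerminalPosition <- function(kind = c("N", "C"), coordinate, reference,
                             strand = NA) {
  kind <- match.arg(kind)
  if (kind == "N") {
    if (missing(coordinate)) coordinate <- 1L
    new("NTerminalPosition", coordinate = as.integer(coordinate),
        reference = as.character(reference), strand = asStrand(strand))
  } else {
    new("CTerminalPosition", coordinate = as.integer(coordinate),
        reference = as.character(reference), strand = asStrand(strand))
  }
}

#' Create an in-range (interval-bounded) fuzzy position
#'
#' @param lowBound,highBound \code{Position} objects, bare coordinates, or
#'   \code{NULL} for an unbounded side; at least one must be given.
#' @inheritParams ExactPosition
#' @return An \code{InRangePosition}.
#' @export
InRangePosition <- function(lowBound = NULL, highBound = NULL, reference,
                            strand = NA) {
  coerce <- function(x) {
    if (is.null(x) || is(x, "Position")) x
    else ExactPosition(x, reference)
  }
  new("InRangePosition", lowBound = coerce(lowBound),
      highBound = coerce(highBound),
      reference = as.character(reference), strand = asStrand(strand))
}

#' Create a one-of (candidate set) fuzzy position
#'
#' @param options list of candidate \code{Position}s (or bare coordinates);
#'   at least two distinct.
#' @inheritParams ExactPosition
#' @return A \code{OneOfPosition}.
#' @export
OneOfPosition <- function(options, reference, strand = NA) {
  options <- lapply(options, function(x)
    if (is(x, "Position")) x else ExactPosition(x, reference))
  new("OneOfPosition", options = options,
      reference = as.character(reference), strand = asStrand(strand))
}

#' Create an in-between position
#'
#' @param after,before the flanking \code{Position}s (or bare coordinates);
#'   the point lies between them.
#' @inheritParams ExactPosition
#' @return An \code{InBetweenPosition}.
#' @export
InBetweenPosition <- function(after, before, reference = NULL, strand = NA) {
  if (!is(after, "Position")) after <- ExactPosition(after, reference)
  if (!is(before, "Position")) before <- ExactPosition(before, reference)
  if (is.null(reference)) reference <- after@reference
  new("InBetweenPosition", after = after, before = before,
      reference = as.character(reference), strand = asStrand(strand))
}

#' Create a region
#'
#' @param begin,end endpoint \code{Position}s; \code{begin} is the biological
#'   start.
#' @return A \code{Region}.
#' @examples
#' chey <- Region(ExactPosition(1965461, "NC_000913.2", "reverse"),
#'                ExactPosition(1965072, "NC_000913.2", "reverse"))
#' @export
Region <- function(begin, end) {
  new("Region", begin = begin, end = end)
}

#' Create a region collection
#'
#' @param members list of \code{Region}s.
#' @param kind \code{"list"} (ordered), \code{"bag"} (unordered) or
#'   \code{"collection"}.
#' @return A \code{RegionCollection}.
#' @export
RegionCollection <- function(members, kind = c("list", "bag", "collection")) {
  kind <- match.arg(kind)
  new("RegionCollection", kind = kind, members = members)
}

#' Create a feature record
#'
#' @param featureId feature identifier (IRI or string).
#' @param locations a single location or list of locations.
#' @param featureType type term, e.g. \code{"gene"}.
#' @param attributes named list of extra attributes.
#' @return A \code{FeatureRecord}.
#' @export
FeatureRecord <- function(featureId, locations, featureType = "region",
                          attributes = list()) {
  if (!is.list(locations)) locations <- list(locations)
  new("FeatureRecord", featureId = as.character(featureId),
      featureType = as.character(featureType), locations = locations,
      attributes = attributes)
}

#' Describe a reference sequence
#'
#' @param id sequence identifier.
#' @param length sequence length in bases (NA if unknown).
#' @param topology \code{"linear"} or \code{"circular"}.
#' @return A \code{ReferenceSequence}.
#' @examples
#' ReferenceSequence("J02448", length = 6407, topology = "circular")
#' @export
ReferenceSequence <- function(id, length = NA_integer_,
                              topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  new("ReferenceSequence", id = as.character(id),
      length = as.integer(length), topology = topology)
}
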