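## Accessors and show methods.  Slot access stays inside the package; user
## code goes through these.

#' @describeIn Position-class reference sequence identifier
#' @param x a model object
#' @export
setMethod("reference", "Position", function(x) x@reference)

#' @describeIn Position-class strand claim ("forward"/"reverse"/"both",
#'   or NA when no claim is made)
#' @export
setMethod("strand", "Position", function(x, ...) x@strand)

#' @describeIn ExactPosition-class 1-based coordinate
#' @export
setMethod("coordinate", "ExactPosition", function(x) x@coordinate)

#' @describeIn Region-class the begin (biological start) position
#' @export
setMethod("beginPosition", "Region", function(x) x@begin)

#' @describeIn Region-class the end (biological end) position
#' @export
setMethod("endPosition", "Region", function(x) x@end)

#' Bounds of an in-range position
#'
#' @param x an \code{InRangePosition}
#' @return a \code{Position} or \code{NULL}
#' @export
lowBound <- function(x) {
  stopifnot(is(x, "InRangePosition"))
  x@lowBound
}

#' @rdname lowBound
#' @export
highBound <- function(x) {
  stopifnot(is(x, "InRangePosition"))
  x@highBound
}

#' Candidate positions of a one-of position
#' @param x a \code{OneOfPosition}
#' @export
positionOptions <- function(x) {
  stopifnot(is(x, "OneOfPosition"))
  x@options
}

#' Flanking positions of an in-between position
#' @param x an \code{InBetweenPosition}
#' @export
afterPosition <- function(x) {
  stopifnot(is(x, "InBetweenPosition"))
  x@after
}

#' @rdname afterPosition
#' @export
beforePosition <- function(x) {
  stopifnot(is(x, "InBetweenPosition"))
  x@before
}

#' Members of a region collection
#' @param x a \code{RegionCollection}
#' @export
collectionMembers <- function(x) {
  stopifnot(is(x, "RegionCollection"))
  x@members
}

#' @rdname collectionMembers
#' @export
collectionKind <- function(x) {
  stopifnot(is(x, "RegionCollection"))
  x@kind
}

#' Feature record accessors
#' @param x a \code{FeatureRecord}
#' @export
featureId <- function(x) {
  stopifnot(is(x, "FeatureRecord"))
  x@featureId
}

#' @rdname featureId
#' @export
featureType <- function(x) {
  stopifnot(is(x, "FeatureRecord"))
  x@featureType
}

#' @rdname featureId
#' @export
featureLocations <- function(x) {
  stopifnot(is(x, "FeatureRecord"))
  x@locations
}

#' @rdname featureId
#' @export
featureAttributes <- function(x) {
  stopifnot(is(x, "FeatureRecord"))
  x@attributes
}

#' Reference sequence accessors
#' @param x a \code{ReferenceSequence}
#' @export
referenceId <- function(x) {
  stopifnot(is(x, "ReferenceSequence"))
  x@id
}

#' @rdname referenceId
#' @export
referenceLength <- function(x) {
  stopifnot(is(x, "ReferenceSequence"))
  x@length
}

#' @rdname referenceId
#' @export
topology <- function(x) {
  stopifnot(is(x, "ReferenceSequence"))
  x@topology
}

#' @rdname referenceId
#' @export
isCircular <- function(x) {
  stopifnot(is(x, "ReferenceSequence"))
  identical(x@topology, "circular")
}

## ---- structural identity --------------------------------------------------

strandTag <- function(strand) if (is.na(strand)) "." else strand

#' Canonical structural key of a position
#'
#' Two positions are equal exactly when their keys are equal: the key encodes
#' the class, the coordinate(s), the strand claim and the reference.  Used
#' for structural equality, for deterministic skolem labels in RDF output and
#' for the hasKey identity merge.
#'
#' @param x a \code{Position}
#' @return character(1)
#' @export
setMethod("positionKey", "ExactPosition", function(x) {
  cls <- if (is(x, "NTerminalPosition")) "NTerm"
         else if (is(x, "CTerminalPosition")) "CTerm"
         else "Exact"
  sprintf("%s/%s/%d/%s", cls, x@reference, x@coordinate, strandTag(x@strand))
})

setMethod("positionKey", "InRangePosition", function(x) {
  lo <- if (is.null(x@lowBound)) "*" else positionKey(x@lowBound)
  hi <- if (is.null(x@highBound)) "*" else positionKey(x@highBound)
  sprintf("InRange/%s/[%s,%s]/%s", x@reference, lo, hi, strandTag(x@strand))
})

setMethod("positionKey", "OneOfPosition", function(x) {
  keys <- sort(vapply(x@options, positionKey, character(1)))
  sprintf("OneOf/%s/{%s}/%s", x@reference, paste(keys, collapse = "|"),
          strandTag(x@strand))
})

setMethod("positionKey", "InBetweenPosition", function(x) {
  sprintf("Between/%s/(%s^%s)/%s", x@reference, positionKey(x@after),
          positionKey(x@before), strandTag(x@strand))
})

#' Structural equality of locations
#'
#' @param a,b locations (\code{Position}, \code{Region} or
#'   \code{RegionCollection}).  Bag collections compare order-insensitively;
#'   list collections compare in order.
#' @return logical(1)
#' @export
locationEqual <- function(a, b) {
  if (is(a, "Position") && is(b, "Position"))
    return(identical(positionKey(a), positionKey(b)))
  if (is(a, "Region") && is(b, "Region"))
    return(locationEqual(a@begin, b@begin) && locationEqual(a@end, b@end))
  if (is(a, "RegionCollection") && is(b, "RegionCollection")) {
    if (!identical(a@kind, b@kind)) return(FALSE)
    if (length(a@members) != length(b@members)) return(FALSE)
    ka <- vapply(a@members, regionKey, character(1))
    kb <- vapply(b@members, regionKey, character(1))
    if (a@kind == "bag") return(identical(sort(ka), sort(kb)))
    return(identical(ka, kb))
  }
  FALSE
}

regionKey <- function(r) {
  sprintf("Region(%s,%s)", positionKey(r@begin), positionKey(r@end))
}

locationKey <- function(loc) {
  if (is(loc, "Position")) positionKey(loc)
  else if (is(loc, "Region")) regionKey(loc)
  else sprintf("%s[%s]", loc@kind,
               paste(vapply(loc@members, regionKey, character(1)),
                     collapse = ";"))
}

## ---- show methods ---------------------------------------------------------

fmtStrand <- function(s) if (is.na(s)) "" else paste0(" (", s, ")")

setMethod("show", "ExactPosition", function(object) {
  cat(sprintf("%s %d on %s%s\n", class(object), object@coordinate,
              object@reference, fmtStrand(object@strand)))
})

setMethod("show", "InRangePosition", function(object) {
  lo <- if (is.null(object@lowBound)) "?" else
    format(fuzzyEnvelopeSafe(object@lowBound)[1])
  hi <- if (is.null(object@highBound)) "?" else
    format(fuzzyEnvelopeSafe(object@highBound)[2])
  cat(sprintf("InRangePosition [%s..%s] on %s%s\n", lo, hi,
              object@reference, fmtStrand(object@strand)))
})

setMethod("show", "OneOfPosition", function(object) {
  cat(sprintf("OneOfPosition {%d options} on %s%s\n",
              length(object@options), object@reference,
              fmtStrand(object@strand)))
})

setMethod("show", "InBetweenPosition", function(object) {
  cat(sprintf("InBetweenPosition between %s and %s\n",
              positionKey(object@after), positionKey(object@before)))
})

setMethod("show", "Region", function(object) {
  cat("Region\n  begin: ")
  show(object@begin)
  cat("  end:   ")
  show(object@end)
})

setMethod("show", "RegionCollection", function(object) {
  cat(sprintf("RegionCollection (%s) with %d member(s)\n", object@kind,
              length(object@members)))
})

setMethod("show", "FeatureRecord", function(object) {
  cat(sprintf("FeatureRecord %s [%s] with %d location(s)\n",
              object@featureId, object@featureType,
              length(object@locations)))
})

setMethod("show", "ReferenceSequence", function(object) {
  len <- if (is.na(object@length)) "unknown length"
         else sprintf("length %d", object@length)
  cat(sprintf("ReferenceSequence %s (%s, %s)\n", object@id, object@topology,
              len))
})
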