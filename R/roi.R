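## Region-of-interest overlap queries over feature records.
##
## Features are reduced to their normalized arcs (fuzzy positions via their
## outer envelope — "possible overlap" semantics; origin-spanning features
## contribute one arc per wrap segment) and indexed per reference in a
## Nested Containment List (NCL): intervals sorted by start with ties
## broken by descending end; an interval contained in its predecessor
## becomes a child, so each list level is containment-free and therefore
## sorted by both start and end, allowing binary-search pruning.  Overlap
## is closed-interval intersection on arcs, strand-blind; strand filtering
## is a separate post-filter.

#' ROI index over feature arcs
#'
#' @slot arcs data.frame of every indexed arc: \code{ref}, \code{start},
#'   \code{end}, \code{id}, \code{strand}
#' @slot ncl per-reference nested containment list structures
#' @slot refLengths named integer vector of known reference lengths
#' @slot warnings character; features indexed only partially
#' @aliases RoiIndex-class
#' @exportClass RoiIndex
setClass("RoiIndex", representation(
  arcs = "data.frame", ncl = "list", refLengths = "integer",
  warnings = "character"))

setMethod("show", "RoiIndex", function(object) {
  cat(sprintf("RoiIndex: %d arcs on %d reference(s)\n",
              nrow(object@arcs), length(object@ncl)))
})

## arcs of one location for indexing; fuzzy envelopes, wrap splitting
indexArcs <- function(loc, ref) {
  tryCatch({
    a <- normalizedArcs(loc, ref)
    list(arcs = a, warning = NULL)
  },
  UnboundedEnvelope = function(e) {
    ## keep the known bound side as a point arc
    env <- knownBoundArc(loc)
    list(arcs = env,
         warning = "unbounded fuzzy side: indexed by its known bound only")
  })
}

knownBoundArc <- function(loc) {
  p <- if (is(loc, "Region")) loc@begin else loc
  known <- function(q) {
    if (is(q, "InRangePosition")) {
      b <- if (!is.null(q@lowBound)) q@lowBound else q@highBound
      fuzzyEnvelope(b)[1]
    } else fuzzyEnvelope(q)[1]
  }
  coords <- if (is(loc, "Region")) c(known(loc@begin), known(loc@end))
            else known(loc)
  data.frame(start = min(coords), end = max(coords))
}

buildNcl <- function(start, end) {
  o <- order(start, -end, method = "radix")
  s <- start[o]; e <- end[o]
  n <- length(s)
  parent <- integer(n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    while (length(stack) && e[stack[length(stack)]] < e[i])
      stack <- stack[-length(stack)]
    parent[i] <- if (length(stack)) stack[length(stack)] else 0L
    stack <- c(stack, i)
  }
  children <- split(seq_len(n), parent)
  top <- children[["0"]]
  children[["0"]] <- NULL
  kids <- vector("list", n)
  for (nm in names(children)) kids[[as.integer(nm)]] <- children[[nm]]
  list(start = s, end = e, order = o, top = top, kids = kids)
}

queryNclList <- function(ncl, members, qmin, qmax, hits) {
  if (length(members) == 0L) return(hits)
  ends <- ncl$end[members]
  ## first member whose end reaches the query window
  lo <- 1L; hi <- length(members)
  if (ends[hi] < qmin) return(hits)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (ends[mid] < qmin) lo <- mid + 1L else hi <- mid
  }
  for (j in lo:length(members)) {
    i <- members[j]
    if (ncl$start[i] > qmax) break
    hits <- c(hits, i)
    hits <- queryNclList(ncl, ncl$kids[[i]], qmin, qmax, hits)
  }
  hits
}

#' Build an ROI index over feature records
#'
#' @param features list of \code{FeatureRecord}s
#' @param refs named list of \code{ReferenceSequence}s (topology and length
#'   drive wrap splitting and envelope bounding); references absent from
#'   the list are treated as linear with unknown length
#' @return a \code{RoiIndex}
#' @export
buildRoiIndex <- function(features, refs = list()) {
  rows <- list()
  warnings <- character()
  for (f in features) {
    for (loc in f@locations) {
      refId <- locationReferenceId(loc)
      res <- indexArcs(loc, refs[[refId]])
      if (!is.null(res$warning))
        warnings <- c(warnings, sprintf("%s: %s", f@featureId, res$warning))
      s <- locationStrand(loc)
      strandTagVal <- if (is.null(s)) "mixed" else if (is.na(s)) "." else s
      rows[[length(rows) + 1L]] <- data.frame(
        ref = refId, start = res$arcs$start, end = res$arcs$end,
        id = f@featureId, strand = strandTagVal, stringsAsFactors = FALSE)
    }
  }
  arcs <- if (length(rows)) unique(do.call(rbind, rows)) else
    data.frame(ref = character(), start = integer(), end = integer(),
               id = character(), strand = character(),
               stringsAsFactors = FALSE)
  rownames(arcs) <- NULL
  ncl <- lapply(split(seq_len(nrow(arcs)), arcs$ref), function(ix) {
    structure(buildNcl(arcs$start[ix], arcs$end[ix]), rows = ix)
  })
  lens <- vapply(refs, function(r) r@length, integer(1))
  names(lens) <- vapply(refs, function(r) r@id, character(1))
  new("RoiIndex", arcs = arcs, ncl = ncl,
      refLengths = lens[!is.na(lens)], warnings = warnings)
}

collectHits <- function(idx, refId, qmin, qmax) {
  ncl <- idx@ncl[[refId]]
  if (is.null(ncl)) return(integer())
  local <- queryNclList(ncl, ncl$top, qmin, qmax, integer())
  attr(ncl, "rows")[ncl$order[local]]
}

#' Query an ROI index
#'
#' Returns the identifiers of all features with at least one base of
#' closed-interval overlap with \code{[qmin, qmax]} on \code{refId},
#' sorted by (minimum matched arc coordinate, feature id).  A query with
#' \code{qmin > qmax} on a circular reference of known length wraps: it is
#' split into \code{[qmin, L]} and \code{[1, qmax]} and the results
#' unioned.  Unknown references yield an empty result.
#'
#' @param idx a \code{RoiIndex}
#' @param refId reference identifier
#' @param qmin,qmax query window (1-based inclusive)
#' @param strand optional \code{"forward"}/\code{"reverse"} post-filter on
#'   the feature's strand claim
#' @return character vector of feature identifiers
#' @export
roiQuery <- function(idx, refId, qmin, qmax, strand = NULL) {
  stopifnot(qmin >= 1L)
  if (qmin > qmax) {
    L <- idx@refLengths[refId]
    if (is.na(L))
      stopFaldor("MissingLength",
        "wrapped query needs a known circular reference length")
    rows <- union(collectHits(idx, refId, qmin, as.integer(L)),
                  collectHits(idx, refId, 1L, qmax))
  } else {
    rows <- collectHits(idx, refId, qmin, qmax)
  }
  if (length(rows) == 0L) return(character())
  hits <- idx@arcs[rows, , drop = FALSE]
  if (!is.null(strand)) hits <- hits[hits$strand == strand, , drop = FALSE]
  if (nrow(hits) == 0L) return(character())
  minStart <- tapply(hits$start, hits$id, min)
  ids <- names(minStart)
  ids[order(unname(minStart), ids, method = "radix")]
}

#' Naive linear-scan ROI query (oracle)
#'
#' Scans every indexed arc; used as the brute-force oracle the NCL results
#' must match exactly.
#'
#' @inheritParams roiQuery
#' @return character vector of feature identifiers in the same order
#'   contract as \code{\link{roiQuery}}
#' @export
roiQueryNaive <- function(idx, refId, qmin, qmax, strand = NULL) {
  stopifnot(qmin >= 1L)
  arcs <- idx@arcs[idx@arcs$ref == refId, , drop = FALSE]
  if (!is.null(strand)) arcs <- arcs[arcs$strand == strand, , drop = FALSE]
  if (qmin > qmax) {
    L <- idx@refLengths[refId]
    if (is.na(L))
      stopFaldor("MissingLength",
        "wrapped query needs a known circular reference length")
    keep <- (arcs$end >= qmin & arcs$start <= L) |
            (arcs$end >= 1L & arcs$start <= qmax)
  } else {
    keep <- arcs$end >= qmin & arcs$start <= qmax
  }
  hits <- arcs[keep, , drop = FALSE]
  if (nrow(hits) == 0L) return(character())
  minStart <- tapply(hits$start, hits$id, min)
  ids <- names(minStart)
  ids[order(unname(minStart), ids, method = "radix")]
}
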