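## INSDC feature-table location strings <-> the location model.
##
## Grammar handled (nestable):
##   N | N..M | N^M | <N | >N | N.M | (N.M)..(P.Q) | acc:loc |
##   complement(loc) | join(loc, ...) | order(loc, ...)
##
## Semantics:
##   * plain "a..b" is a forward-strand region with begin = a, end = b;
##   * "complement(a..b)" is a reverse-strand region whose *biological*
##     start is b (begin = b, end = a) — the complement string reads as
##     complement(end..start);
##   * join(...) preserves order (ListOfRegions), order(...) does not
##     (BagOfRegions);
##   * fuzzy operators: "<N" bounds the position from above only (it lies at
##     or before N), ">N" from below only, "N.M" is an in-range position,
##     "N^M" a point between two adjacent bases;
##   * "acc:..." sets the reference of the enclosed location to acc
##     (remote reference), otherwise the supplied default reference is used.

refIdOf <- function(ref) {
  if (is(ref, "ReferenceSequence")) ref@id else as.character(ref)
}

## ---- parser ---------------------------------------------------------------

newCursor <- function(s) {
  env <- new.env(parent = emptyenv())
  env$s <- s
  env$pos <- 1L
  env$n <- nchar(s)
  env
}

skipWs <- function(cur) {
  while (cur$pos <= cur$n &&
         substr(cur$s, cur$pos, cur$pos) %in% c(" ", "\t", "\n"))
    cur$pos <- cur$pos + 1L
}

peekChar <- function(cur) {
  if (cur$pos > cur$n) "" else substr(cur$s, cur$pos, cur$pos)
}

parseError <- function(cur, what) {
  stopFaldor("ParseError",
    sprintf("location syntax error at offset %d: expected %s in \"%s\"",
            cur$pos, what, cur$s), offset = cur$pos)
}

expectChar <- function(cur, ch) {
  if (peekChar(cur) != ch) parseError(cur, sprintf("'%s'", ch))
  cur$pos <- cur$pos + 1L
}

matchAhead <- function(cur, pattern) {
  rest <- substr(cur$s, cur$pos, cur$n)
  m <- regmatches(rest, regexpr(pattern, rest, perl = TRUE))
  if (length(m) == 0L) return(NULL)
  m
}

takeNumber <- function(cur) {
  m <- matchAhead(cur, "^[0-9]+")
  if (is.null(m)) parseError(cur, "a coordinate")
  cur$pos <- cur$pos + nchar(m)
  v <- suppressWarnings(as.numeric(m))
  if (is.na(v) || v < 1)
    stopFaldor("InvalidCoordinate",
      sprintf("coordinate must be a positive integer, got \"%s\"", m))
  as.integer(v)
}

## one endpoint: exact, <N, >N, N.M, (N.M)
parsePoint <- function(cur, ref) {
  skipWs(cur)
  ch <- peekChar(cur)
  if (ch == "<") {
    cur$pos <- cur$pos + 1L
    n <- takeNumber(cur)
    return(InRangePosition(highBound = n, reference = ref,
                           strand = "forward"))
  }
  if (ch == ">") {
    cur$pos <- cur$pos + 1L
    n <- takeNumber(cur)
    return(InRangePosition(lowBound = n, reference = ref,
                           strand = "forward"))
  }
  if (ch == "(") {
    cur$pos <- cur$pos + 1L
    lo <- takeNumber(cur)
    expectChar(cur, ".")
    hi <- takeNumber(cur)
    expectChar(cur, ")")
    return(InRangePosition(lowBound = lo, highBound = hi, reference = ref,
                           strand = "forward"))
  }
  n <- takeNumber(cur)
  ## bare "N.M" in-range (single dot, not "..")
  if (peekChar(cur) == "." &&
      substr(cur$s, cur$pos + 1L, cur$pos + 1L) != ".") {
    cur$pos <- cur$pos + 1L
    m <- takeNumber(cur)
    return(InRangePosition(lowBound = n, highBound = m, reference = ref,
                           strand = "forward"))
  }
  ExactPosition(n, ref, strand = "forward")
}

parseSimple <- function(cur, ref) {
  m <- matchAhead(cur, "^[A-Za-z][A-Za-z0-9_.]*:")
  if (!is.null(m)) {
    cur$pos <- cur$pos + nchar(m)
    ref <- substr(m, 1L, nchar(m) - 1L)
  }
  p1 <- parsePoint(cur, ref)
  if (peekChar(cur) == "." &&
      substr(cur$s, cur$pos + 1L, cur$pos + 1L) == ".") {
    cur$pos <- cur$pos + 2L
    p2 <- parsePoint(cur, ref)
    return(Region(p1, p2))
  }
  if (peekChar(cur) == "^") {
    cur$pos <- cur$pos + 1L
    if (!is(p1, "ExactPosition")) parseError(cur, "exact base before '^'")
    n2 <- takeNumber(cur)
    return(InBetweenPosition(after = p1,
                             before = ExactPosition(n2, p1@reference,
                                                    strand = "forward"),
                             reference = p1@reference, strand = "forward"))
  }
  p1
}

parseCompound <- function(cur, ref, kind) {
  expectChar(cur, "(")
  skipWs(cur)
  if (peekChar(cur) == ")")
    stopFaldor("EmptyCompound", sprintf("%s() must have members", kind))
  members <- list()
  repeat {
    members[[length(members) + 1L]] <- parseLocation(cur, ref)
    skipWs(cur)
    if (peekChar(cur) == ",") {
      cur$pos <- cur$pos + 1L
      next
    }
    break
  }
  expectChar(cur, ")")
  members <- lapply(members, asRegionMember)
  RegionCollection(members, kind = if (kind == "join") "list" else "bag")
}

asRegionMember <- function(loc) {
  if (is(loc, "Region")) loc
  else if (is(loc, "Position")) Region(loc, loc)
  else stopFaldor("ParseError",
    "nested join/order inside a compound location is not supported")
}

parseLocation <- function(cur, ref) {
  skipWs(cur)
  if (!is.null(matchAhead(cur, "^complement\\("))) {
    cur$pos <- cur$pos + nchar("complement")
    expectChar(cur, "(")
    inner <- parseLocation(cur, ref)
    skipWs(cur)
    expectChar(cur, ")")
    return(complementLocation(inner))
  }
  if (!is.null(matchAhead(cur, "^join\\("))) {
    cur$pos <- cur$pos + nchar("join")
    return(parseCompound(cur, ref, "join"))
  }
  if (!is.null(matchAhead(cur, "^order\\("))) {
    cur$pos <- cur$pos + nchar("order")
    return(parseCompound(cur, ref, "order"))
  }
  parseSimple(cur, ref)
}

flipStrand <- function(s) {
  if (is.na(s)) "reverse"
  else switch(s, forward = "reverse", reverse = "forward", both = "both")
}

flipPosition <- function(p) {
  p@strand <- flipStrand(p@strand)
  if (is(p, "InRangePosition")) {
    if (!is.null(p@lowBound)) p@lowBound <- flipPosition(p@lowBound)
    if (!is.null(p@highBound)) p@highBound <- flipPosition(p@highBound)
  } else if (is(p, "OneOfPosition")) {
    p@options <- lapply(p@options, flipPosition)
  } else if (is(p, "InBetweenPosition")) {
    p@after <- flipPosition(p@after)
    p@before <- flipPosition(p@before)
  }
  p
}

#' Complement a location
#'
#' Flips the strand claim of every position and swaps begin/end of every
#' region so that begin remains the biological start.  For ordered
#' collections the member order is also reversed, preserving transcription
#' order.
#'
#' @param loc a location
#' @return the complemented location
#' @export
complementLocation <- function(loc) {
  if (is(loc, "Position")) return(flipPosition(loc))
  if (is(loc, "Region"))
    return(Region(flipPosition(loc@end), flipPosition(loc@begin)))
  members <- rev(lapply(loc@members, complementLocation))
  RegionCollection(members, kind = loc@kind)
}

#' Parse an INSDC location string
#'
#' @param s the location string, e.g. \code{"complement(1965072..1965461)"}
#'   or \code{"join(6006..6407,1..831)"}
#' @param defaultRef reference the coordinates are counted on (a
#'   \code{ReferenceSequence} or an identifier string); remote
#'   \code{acc:...} segments override it
#' @return a \code{Region}, \code{Position} or \code{RegionCollection}
#' @examples
#' chey <- parseInsdc("complement(1965072..1965461)", "NC_000913.2")
#' coordinate(beginPosition(chey))  # 1965461, the biological start
#' @export
parseInsdc <- function(s, defaultRef = "unnamed") {
  stopifnot(is.character(s), length(s) == 1L)
  ref <- refIdOf(defaultRef)
  cur <- newCursor(s)
  loc <- parseLocation(cur, ref)
  skipWs(cur)
  if (cur$pos <= cur$n)
    parseError(cur, "end of string")
  loc
}

## ---- serializer -----------------------------------------------------------

positionStrandOf <- function(p) p@strand

## uniform strand of a location, NA if untyped, NULL if mixed
locationStrand <- function(loc) {
  strands <- collectStrands(loc)
  strands <- strands[!is.na(strands)]
  if (length(strands) == 0L) return(NA_character_)
  u <- unique(strands)
  if (length(u) == 1L) u else NULL
}

collectStrands <- function(loc) {
  if (is(loc, "Region"))
    c(collectStrands(loc@begin), collectStrands(loc@end))
  else if (is(loc, "RegionCollection"))
    unlist(lapply(loc@members, collectStrands))
  else loc@strand
}

serializePoint <- function(p, defaultRef, asEndpoint = FALSE) {
  prefix <- if (!identical(p@reference, defaultRef) && !asEndpoint)
    paste0(p@reference, ":") else ""
  if (is(p, "ExactPosition"))
    return(paste0(prefix, p@coordinate))
  if (is(p, "InRangePosition")) {
    hasLo <- !is.null(p@lowBound); hasHi <- !is.null(p@highBound)
    if (hasLo && hasHi) {
      lo <- fuzzyEnvelope(p@lowBound)[1]
      hi <- fuzzyEnvelope(p@highBound)[2]
      body <- if (asEndpoint) sprintf("(%d.%d)", lo, hi)
              else sprintf("%d.%d", lo, hi)
      return(paste0(prefix, body))
    }
    if (hasHi) return(paste0(prefix, "<", fuzzyEnvelope(p@highBound)[2]))
    return(paste0(prefix, ">", fuzzyEnvelope(p@lowBound)[1]))
  }
  if (is(p, "InBetweenPosition")) {
    a <- p@after; b <- p@before
    if (!is(a, "ExactPosition") || !is(b, "ExactPosition"))
      stopFaldor("NotExpressible",
                 "in-between position with fuzzy neighbours")
    return(paste0(prefix, a@coordinate, "^", b@coordinate))
  }
  stopFaldor("NotExpressible",
    sprintf("%s has no INSDC location syntax", class(p)))
}

## endpoint pair with a possible remote prefix on the region
serializeForwardRegion <- function(r, defaultRef) {
  refA <- r@begin@reference; refB <- r@end@reference
  if (!identical(refA, refB))
    stopFaldor("NotExpressible",
      "region endpoints on different references cannot be written in INSDC")
  prefix <- if (!identical(refA, defaultRef)) paste0(refA, ":") else ""
  paste0(prefix,
         serializePoint(r@begin, refA, asEndpoint = TRUE), "..",
         serializePoint(r@end, refA, asEndpoint = TRUE))
}

#' Serialize a location to an INSDC location string
#'
#' Inverse of \code{\link{parseInsdc}}: reverse-strand regions re-emit the
#' canonical \code{complement(min..max)} form, ordered collections become
#' \code{join(...)}, unordered ones \code{order(...)}.
#'
#' @param loc the location
#' @param defaultRef the reference identifier that may stay implicit;
#'   endpoints on any other reference get an \code{acc:} prefix
#' @return character(1)
#' @examples
#' r <- Region(ExactPosition(1965461, "NC_000913.2", "reverse"),
#'             ExactPosition(1965072, "NC_000913.2", "reverse"))
#' serializeInsdc(r, "NC_000913.2")  # "complement(1965072..1965461)"
#' @export
serializeInsdc <- function(loc, defaultRef = "unnamed") {
  defaultRef <- refIdOf(defaultRef)
  s <- locationStrand(loc)
  if (is.null(s))
    stopFaldor("NotExpressible",
      "mixed-strand locations cannot be written as one INSDC string")
  if (!is.na(s) && s == "both")
    stopFaldor("NotExpressible",
      "both-strands positions have no INSDC location syntax")
  if (!is.na(s) && s == "reverse")
    return(paste0("complement(",
                  serializeInsdc(complementLocation(loc), defaultRef), ")"))
  if (is(loc, "Position"))
    return(serializePoint(loc, defaultRef))
  if (is(loc, "Region"))
    return(serializeForwardRegion(loc, defaultRef))
  if (length(loc@members) == 0L)
    stopFaldor("EmptyCompound", "cannot serialize an empty collection")
  keyword <- if (loc@kind == "bag") "order" else "join"
  inner <- vapply(loc@members, serializeInsdc, character(1),
                  defaultRef = defaultRef)
  paste0(keyword, "(", paste(inner, collapse = ","), ")")
}

## ---- circular origin collapse --------------------------------------------

memberIsExact <- function(r) {
  is(r@begin, "ExactPosition") && is(r@end, "ExactPosition")
}

#' Collapse an origin-spanning join into a single region
#'
#' INSDC splits a feature crossing the origin of a circular replicon into
#' \code{join(a..L, 1..b)}.  On a circular reference of known length this is
#' one biological region; this function rewrites the two-member ordered
#' collection into \code{Region(begin = a, end = b)}.  Inputs that do not
#' match the origin-adjacency pattern (wrong topology, more members, gaps)
#' are returned unchanged.
#'
#' @param col a \code{RegionCollection} (only \code{"list"} collections are
#'   candidates; \code{order(...)} semantics are too weak to collapse)
#' @param ref the \code{ReferenceSequence}; must be circular with known
#'   length for a collapse to happen
#' @return a single \code{Region} if collapsed, otherwise \code{col}
#' @examples
#' loc <- parseInsdc("join(6006..6407,1..831)", "J02448")
#' ref <- ReferenceSequence("J02448", 6407, "circular")
#' collapsed <- collapseOriginJoin(loc, ref)
#' coordinate(beginPosition(collapsed))  # 6006
#' @export
collapseOriginJoin <- function(col, ref) {
  if (!is(col, "RegionCollection") || col@kind != "list") return(col)
  if (!is(ref, "ReferenceSequence") || !isCircular(ref)) return(col)
  if (length(col@members) != 2L) return(col)
  m1 <- col@members[[1L]]; m2 <- col@members[[2L]]
  if (!memberIsExact(m1) || !memberIsExact(m2)) return(col)
  refs <- c(m1@begin@reference, m1@end@reference,
            m2@begin@reference, m2@end@reference)
  if (length(unique(refs)) != 1L || !identical(refs[1], ref@id)) return(col)
  strands <- c(m1@begin@strand, m1@end@strand, m2@begin@strand,
               m2@end@strand)
  if (length(unique(strands)) != 1L) return(col)
  s <- strands[1]
  rev <- !is.na(s) && s == "reverse"
  touchesOrigin <- if (rev)
    m1@end@coordinate == 1L else m2@begin@coordinate == 1L
  if (!touchesOrigin) return(col)
  if (is.na(ref@length))
    stopFaldor("MissingLength",
      "cannot test origin adjacency: circular reference length unknown")
  touchesLength <- if (rev)
    m2@begin@coordinate == ref@length else m1@end@coordinate == ref@length
  if (!touchesLength) return(col)
  Region(m1@begin, m2@end)
}

#' Split an origin-spanning region into an explicit two-member join
#'
#' Inverse of \code{\link{collapseOriginJoin}}: a region that wraps the
#' origin of a circular reference becomes the ordered two-member collection
#' INSDC notation requires.  Non-wrapping regions are returned unchanged.
#'
#' @param r a \code{Region}
#' @param ref the circular \code{ReferenceSequence} (known length)
#' @return a \code{RegionCollection} of kind \code{"list"}, or \code{r}
#' @export
expandOriginJoin <- function(r, ref) {
  if (!is(r, "Region") || !is(ref, "ReferenceSequence") ||
      !isCircular(ref) || is.na(ref@length))
    return(r)
  if (!memberIsExact(r)) return(r)
  s <- r@begin@strand
  b <- r@begin@coordinate; e <- r@end@coordinate
  rev <- !is.na(s) && s == "reverse"
  wraps <- if (rev) b < e else b > e
  if (!wraps) return(r)
  mk <- function(coord) ExactPosition(coord, r@begin@reference, s)
  if (rev)
    RegionCollection(list(Region(r@begin, mk(1L)),
                          Region(mk(ref@length), r@end)), kind = "list")
  else
    RegionCollection(list(Region(r@begin, mk(ref@length)),
                          Region(mk(1L), r@end)), kind = "list")
}

#' Explode a compound location into its member regions
#'
#' Gene models stored as \code{join(...)} of exon ranges are better
#' described as individual exon regions; this returns the members as
#' standalone regions, preserving file order.  The \code{"ordered"}
#' attribute records whether member order was meaningful (\code{join}) or
#' not (\code{order}).
#'
#' @param col a \code{RegionCollection}
#' @return list of \code{Region}s with attribute \code{ordered}
#' @export
explodeExons <- function(col) {
  stopifnot(is(col, "RegionCollection"))
  out <- col@members
  attr(out, "ordered") <- identical(col@kind, "list")
  out
}
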