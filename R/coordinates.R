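## Convention conversions: GFF3/GTF (1-based, inclusive, start <= end
## regardless of strand) and BED (0-based, half-open) to and from the
## biologically oriented region model.
##
## The conversions preserve the *set of covered bases* exactly; what changes
## is bookkeeping: which endpoint is called the start, and where counting
## begins.  For a reverse-strand GFF line the biological start is the
## numerically larger coordinate, so begin = end-column and end =
## start-column.

#' GFF-style coordinates
#'
#' A validated container for one GFF3/GTF interval: \code{start} and
#' \code{end} are 1-based inclusive with \code{start <= end} always;
#' \code{strand} is one of \code{"+"}, \code{"-"}, \code{"."} (none) or
#' \code{"?"} (relevant but unknown).
#'
#' @param seqid reference sequence name
#' @param start,end 1-based inclusive interval, \code{start <= end}
#' @param strand \code{"+"}, \code{"-"}, \code{"."} or \code{"?"}
#' @return a \code{GffCoordinates} object (a named list)
#' @export
GffCoordinates <- function(seqid, start, end, strand = ".") {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || start > end)
    stopFaldor("InvalidInterval",
      sprintf("GFF interval requires 1 <= start <= end, got %s..%s",
              start, end))
  if (!strand %in% c("+", "-", ".", "?"))
    stopFaldor("InvalidStrand", sprintf("bad GFF strand: %s", strand))
  structure(list(seqid = as.character(seqid), start = start, end = end,
                 strand = strand), class = "GffCoordinates")
}

#' BED-style coordinates
#'
#' \code{chromStart} is 0-based, \code{chromEnd} exclusive, so the first
#' base of a sequence is \code{(0, 1)}; empty intervals are invalid.
#'
#' @param chrom reference sequence name
#' @param chromStart 0-based start
#' @param chromEnd exclusive end, \code{chromStart < chromEnd}
#' @param strand \code{"+"}, \code{"-"} or \code{NA} when absent
#' @return a \code{BedCoordinates} object (a named list)
#' @export
BedCoordinates <- function(chrom, chromStart, chromEnd, strand = NA) {
  chromStart <- as.integer(chromStart); chromEnd <- as.integer(chromEnd)
  if (is.na(chromStart) || is.na(chromEnd) || chromStart < 0L ||
      chromStart >= chromEnd)
    stopFaldor("InvalidInterval",
      sprintf("BED interval requires 0 <= chromStart < chromEnd, got %s/%s",
              chromStart, chromEnd))
  if (!is.na(strand) && !strand %in% c("+", "-"))
    stopFaldor("InvalidStrand", sprintf("bad BED strand: %s", strand))
  structure(list(chrom = as.character(chrom), chromStart = chromStart,
                 chromEnd = chromEnd, strand = strand),
            class = "BedCoordinates")
}

strandFromSymbol <- function(sym) {
  switch(sym, "+" = "forward", "-" = "reverse", NA_character_)
}

strandToSymbol <- function(strand) {
  if (is.na(strand)) "."
  else switch(strand, forward = "+", reverse = "-",
              stopFaldor("NotExpressible",
                sprintf("strand '%s' has no GFF symbol", strand)))
}

#' Convert GFF coordinates to a region
#'
#' \code{"+"} gives begin = start, end = end on the forward strand;
#' \code{"-"} gives begin = end, end = start on the reverse strand (the
#' biological start of a reverse feature is the numerically larger
#' coordinate); \code{"."} and \code{"?"} give untyped positions in numeric
#' order — absence of a strand claim, never an "unknown strand" value.
#'
#' @param g a \code{GffCoordinates}
#' @return a \code{Region}
#' @examples
#' gffToRegion(GffCoordinates("chr1", 1050, 2080, "-"))  # begin 2080
#' @export
gffToRegion <- function(g) {
  stopifnot(inherits(g, "GffCoordinates"))
  s <- strandFromSymbol(g$strand)
  if (identical(g$strand, "-"))
    Region(ExactPosition(g$end, g$seqid, s),
           ExactPosition(g$start, g$seqid, s))
  else
    Region(ExactPosition(g$start, g$seqid, s),
           ExactPosition(g$end, g$seqid, s))
}

regionNumericEndpoints <- function(r) {
  if (!is(r@begin, "ExactPosition") || !is(r@end, "ExactPosition"))
    stopFaldor("NotExpressible",
      "fuzzy endpoints cannot be written as plain interval coordinates")
  if (!identical(r@begin@reference, r@end@reference))
    stopFaldor("NotExpressible",
      "region endpoints on different references")
  sb <- r@begin@strand; se <- r@end@strand
  if (!identical(is.na(sb), is.na(se)) || (!is.na(sb) && sb != se))
    stopFaldor("NotExpressible",
      "region endpoints on different strands have no start<=end rendering")
  b <- r@begin@coordinate; e <- r@end@coordinate
  ## begin/end in an order contradicting the strand orientation means the
  ## region wraps a circular origin (or is malformed); either way it has no
  ## single start<=end rendering and must be split into arcs first
  wrapped <- if (!is.na(sb) && sb == "reverse") b < e else b > e
  if (wrapped)
    stopFaldor("NotExpressible",
      "origin-wrapping region must be split into arcs first")
  list(seqid = r@begin@reference, min = min(b, e), max = max(b, e),
       strand = sb)
}

#' Convert a region to GFF coordinates
#'
#' Inverse of \code{\link{gffToRegion}} on its valid domain: exact,
#' same-strand, same-reference, non-wrapping endpoints.
#'
#' @param r a \code{Region}
#' @return a \code{GffCoordinates}
#' @examples
#' chey <- parseInsdc("complement(1965072..1965461)", "NC_000913.2")
#' regionToGff(chey)  # start 1965072, end 1965461, strand "-"
#' @export
regionToGff <- function(r) {
  stopifnot(is(r, "Region"))
  pe <- regionNumericEndpoints(r)
  GffCoordinates(pe$seqid, pe$min, pe$max, strandToSymbol(pe$strand))
}

#' Convert BED coordinates to a region
#'
#' Translates 0-based half-open to 1-based inclusive
#' (\code{chromStart + 1, chromEnd}), then applies the strand rule of
#' \code{\link{gffToRegion}}.
#'
#' @param b a \code{BedCoordinates}
#' @return a \code{Region}
#' @examples
#' bedToRegion(BedCoordinates("chr1", 1049, 2080, "+"))  # begin 1050
#' @export
bedToRegion <- function(b) {
  stopifnot(inherits(b, "BedCoordinates"))
  gffToRegion(GffCoordinates(b$chrom, b$chromStart + 1L, b$chromEnd,
                             if (is.na(b$strand)) "." else b$strand))
}

#' Convert a region to BED coordinates
#'
#' Inverse of \code{\link{bedToRegion}}: \code{chromStart = min - 1},
#' \code{chromEnd = max}.
#'
#' @param r a \code{Region}
#' @return a \code{BedCoordinates}
#' @export
regionToBed <- function(r) {
  stopifnot(is(r, "Region"))
  pe <- regionNumericEndpoints(r)
  s <- if (is.na(pe$strand)) NA_character_
       else switch(pe$strand, forward = "+", reverse = "-",
                   stopFaldor("NotExpressible",
                     sprintf("strand '%s' has no BED symbol", pe$strand)))
  BedCoordinates(pe$seqid, pe$min - 1L, pe$max, s)
}
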