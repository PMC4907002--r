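## File-level readers and writers: GFF3, BED, INSDC feature tables, Turtle.
##
## Readers are deliberately tolerant: malformed lines are skipped with a
## line-level warning collected in the ConversionReport, never a hard stop,
## so one bad line cannot sink a conversion run.  All readers accept "-"
## for standard input.
##
## Lossless-round-trip bookkeeping: GFF columns the model does not
## interpret (source, score, phase) ride along as reserved attributes, and
## a GFF strand of "?" (unknown-but-relevant) is recorded as an attribute
## on top of the untyped positions so writing reproduces it.  Fuzzy
## locations exported to interval-only formats are written as their outer
## envelope plus a lossy-conversion flag, never silently truncated.

#' Conversion report
#'
#' @slot nRead number of content lines (or features) seen
#' @slot nConverted number of feature records produced
#' @slot nCollapsedJoins number of origin-spanning joins collapsed into a
#'   single region
#' @slot warnings data.frame with columns \code{line}, \code{message}
#' @aliases ConversionReport-class
#' @exportClass ConversionReport
setClass("ConversionReport", representation(
  nRead = "integer", nConverted = "integer", nCollapsedJoins = "integer",
  warnings = "data.frame"))

setValidity("ConversionReport", function(object) {
  if (object@nConverted > object@nRead)
    "nConverted cannot exceed nRead"
  else TRUE
})

setMethod("show", "ConversionReport", function(object) {
  cat(sprintf(
    "ConversionReport: %d read, %d converted, %d joins collapsed, %d warning(s)\n",
    object@nRead, object@nConverted, object@nCollapsedJoins,
    nrow(object@warnings)))
})

newReport <- function(nRead, nConverted, nCollapsedJoins, warnings) {
  if (length(warnings) == 0L)
    wdf <- data.frame(line = integer(), message = character(),
                      stringsAsFactors = FALSE)
  else
    wdf <- do.call(rbind, lapply(warnings, function(w)
      data.frame(line = w$line, message = w$message,
                 stringsAsFactors = FALSE)))
  new("ConversionReport", nRead = as.integer(nRead),
      nConverted = as.integer(nConverted),
      nCollapsedJoins = as.integer(nCollapsedJoins), warnings = wdf)
}

#' @rdname ConversionReport-class
#' @param x a \code{ConversionReport}
#' @export
reportWarnings <- function(x) x@warnings

#' @rdname ConversionReport-class
#' @export
nRead <- function(x) x@nRead

#' @rdname ConversionReport-class
#' @export
nConverted <- function(x) x@nConverted

#' @rdname ConversionReport-class
#' @export
nCollapsedJoins <- function(x) x@nCollapsedJoins

readInputLines <- function(path) {
  if (identical(path, "-")) return(readLines(file("stdin")))
  if (!file.exists(path))
    stopFaldor("IOFailure", sprintf("cannot read %s", path))
  readLines(path)
}

## GFF3 column-9 percent-encoding
gffEscape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  x <- gsub("\t", "%09", x, fixed = TRUE)
  x
}

gffUnescape <- function(x) utils::URLdecode(x)

parseGffAttributes <- function(col9) {
  if (col9 %in% c("", ".")) return(list())
  parts <- strsplit(col9, ";", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  out <- list()
  for (p in parts) {
    eq <- regexpr("=", p, fixed = TRUE)
    if (eq < 0) {
      out[[gffUnescape(p)]] <- ""
    } else {
      key <- gffUnescape(substr(p, 1, eq - 1))
      out[[key]] <- gffUnescape(substr(p, eq + 1, nchar(p)))
    }
  }
  out
}

formatGffAttributes <- function(attrs) {
  if (length(attrs) == 0L) return(".")
  paste(vapply(names(attrs), function(k)
    paste0(gffEscape(k), "=", gffEscape(as.character(attrs[[k]]))),
    character(1)), collapse = ";")
}

GFF_RESERVED <- c(".gff_source", ".gff_score", ".gff_phase",
                  ".gff_strand_unknown", ".lossy_fuzzy", ".origin_wrap",
                  ".bed_score")

#' Read a GFF3 file into feature records
#'
#' One record per feature line, converted through
#' \code{\link{gffToRegion}}.  \code{##} directives are preserved as the
#' \code{directives} attribute of the returned list; comment lines and
#' malformed lines (wrong column count, start > end) are skipped with a
#' warning in the report.
#'
#' @param path file path or \code{"-"} for standard input
#' @return list with elements \code{records} (list of
#'   \code{FeatureRecord}s), \code{report} (a \code{ConversionReport}) and
#'   \code{directives} (character)
#' @export
readGff3 <- function(path) {
  lines <- readInputLines(path)
  records <- list()
  warnings <- list()
  directives <- character()
  nRead <- 0L
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(trimws(line))) next
    if (startsWith(line, "##")) {
      directives <- c(directives, line)
      next
    }
    if (startsWith(line, "#")) {
      warnings[[length(warnings) + 1L]] <-
        list(line = i, message = "comment line skipped")
      next
    }
    nRead <- nRead + 1L
    cols <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(cols) != 9L) {
      warnings[[length(warnings) + 1L]] <-
        list(line = i, message = sprintf("expected 9 columns, got %d",
                                         length(cols)))
      next
    }
    rec <- tryCatch({
      start <- as.integer(cols[4]); end <- as.integer(cols[5])
      strandSym <- cols[7]
      g <- GffCoordinates(cols[1], start, end,
                          if (strandSym == "?") "." else strandSym)
      region <- gffToRegion(g)
      attrs <- parseGffAttributes(cols[9])
      fid <- if (!is.null(attrs$ID)) attrs$ID
             else sprintf("%s:%d-%d#%d", cols[1], start, end, i)
      if (cols[2] != ".") attrs$.gff_source <- cols[2]
      if (cols[6] != ".") attrs$.gff_score <- cols[6]
      if (cols[8] != ".") attrs$.gff_phase <- cols[8]
      if (strandSym == "?") attrs$.gff_strand_unknown <- "1"
      FeatureRecord(fid, region, featureType = cols[3], attributes = attrs)
    }, error = function(e) e)
    if (is(rec, "error")) {
      warnings[[length(warnings) + 1L]] <-
        list(line = i, message = conditionMessage(rec))
    } else {
      records[[length(records) + 1L]] <- rec
    }
  }
  list(records = records,
       report = newReport(nRead, length(records), 0L, warnings),
       directives = directives)
}

#' Read a BED file (3-6 columns) into feature records
#'
#' Coordinates convert through \code{\link{bedToRegion}}; the name column
#' becomes the feature identifier and the score rides along as an
#' attribute.
#'
#' @inheritParams readGff3
#' @return list with \code{records} and \code{report}
#' @export
readBed <- function(path) {
  lines <- readInputLines(path)
  records <- list()
  warnings <- list()
  nRead <- 0L
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(trimws(line)) || startsWith(line, "#") ||
        startsWith(line, "track") || startsWith(line, "browser")) next
    nRead <- nRead + 1L
    cols <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(cols) < 3L) {
      warnings[[length(warnings) + 1L]] <-
        list(line = i, message = sprintf("expected >= 3 columns, got %d",
                                         length(cols)))
      next
    }
    rec <- tryCatch({
      strandCol <- if (length(cols) >= 6L && cols[6] %in% c("+", "-"))
        cols[6] else NA
      b <- BedCoordinates(cols[1], as.integer(cols[2]), as.integer(cols[3]),
                          strandCol)
      region <- bedToRegion(b)
      fid <- if (length(cols) >= 4L && nzchar(cols[4]) && cols[4] != ".")
        cols[4] else sprintf("%s:%s-%s#%d", cols[1], cols[2], cols[3], i)
      attrs <- list()
      if (length(cols) >= 5L && cols[5] != ".")
        attrs$.bed_score <- cols[5]
      FeatureRecord(fid, region, featureType = "region",
                    attributes = attrs)
    }, error = function(e) e)
    if (is(rec, "error")) {
      warnings[[length(warnings) + 1L]] <-
        list(line = i, message = conditionMessage(rec))
    } else {
      records[[length(records) + 1L]] <- rec
    }
  }
  list(records = records,
       report = newReport(nRead, length(records), 0L, warnings))
}

parseQualifier <- function(line) {
  m <- regmatches(line, regexec("^/([A-Za-z0-9_]+)(=(.*))?$", line))[[1]]
  if (length(m) == 0L) return(NULL)
  val <- if (nchar(m[4]) || nchar(m[3])) m[4] else ""
  val <- sub('^"', "", sub('"$', "", val))
  list(key = m[2], value = val)
}

#' Read an INSDC feature-table snippet into feature records
#'
#' Accepts the five-column feature-table layout of GenBank/EMBL flat files:
#' a feature key with its location string (continuation lines allowed),
#' followed by \code{/qualifier="value"} lines.  Locations parse through
#' \code{\link{parseInsdc}}.  When the reference is circular with known
#' length (via \code{refs}), origin-spanning \code{join(...)}s collapse to
#' a single region and are counted in the report.
#'
#' @inheritParams readGff3
#' @param defaultRef reference identifier for bare coordinates
#' @param refs named list of \code{ReferenceSequence} objects (the
#'   topology/length sidecar: bare feature tables carry no header)
#' @return list with \code{records} and \code{report}
#' @export
readFeatureTable <- function(path, defaultRef = "unnamed", refs = list()) {
  lines <- readInputLines(path)
  entries <- list()   # list of (line, key, location, qualifiers)
  current <- NULL
  inLocation <- FALSE
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(trimws(line)) || startsWith(trimws(line), "#")) next
    stripped <- trimws(line)
    isQualifier <- startsWith(stripped, "/")
    startsAtMargin <- grepl("^\\S", line) ||
      (grepl("^\\s{1,10}\\S", line) && grepl("\\s", trimws(line)))
    if (!isQualifier && grepl("^\\s*[A-Za-z'_0-9-]+\\s+\\S", line)) {
      ## new feature line: key + start of location
      if (!is.null(current)) entries[[length(entries) + 1L]] <- current
      parts <- regmatches(stripped,
                          regexec("^(\\S+)\\s+(\\S.*)$", stripped))[[1]]
      current <- list(line = i, key = parts[2],
                      location = gsub("\\s", "", parts[3]),
                      qualifiers = list())
      inLocation <- TRUE
    } else if (isQualifier) {
      if (is.null(current)) next
      q <- parseQualifier(stripped)
      if (!is.null(q)) current$qualifiers[[q$key]] <- q$value
      inLocation <- FALSE
    } else if (!is.null(current) && inLocation) {
      ## location continuation
      current$location <- paste0(current$location, gsub("\\s", "", stripped))
    }
  }
  if (!is.null(current)) entries[[length(entries) + 1L]] <- current

  records <- list()
  warnings <- list()
  nCollapsed <- 0L
  for (k in seq_along(entries)) {
    e <- entries[[k]]
    rec <- tryCatch({
      loc <- parseInsdc(e$location, defaultRef)
      refId <- locationReferenceId(loc)
      ref <- refs[[refId]]
      if (is(loc, "RegionCollection") && !is.null(ref) && isCircular(ref)) {
        collapsed <- collapseOriginJoin(loc, ref)
        if (is(collapsed, "Region")) {
          loc <- collapsed
          nCollapsed <- nCollapsed + 1L
        }
      }
      fid <- e$qualifiers$gene
      if (is.null(fid)) fid <- e$qualifiers$locus_tag
      if (is.null(fid)) fid <- e$qualifiers$label
      if (is.null(fid)) fid <- sprintf("%s#%d", e$key, e$line)
      FeatureRecord(fid, loc, featureType = e$key,
                    attributes = e$qualifiers)
    }, error = function(err) err)
    if (is(rec, "error")) {
      warnings[[length(warnings) + 1L]] <-
        list(line = e$line, message = conditionMessage(rec))
    } else {
      records[[length(records) + 1L]] <- rec
    }
  }
  list(records = records,
       report = newReport(length(entries), length(records), nCollapsed,
                          warnings))
}

## first reference mentioned by a location
locationReferenceId <- function(loc) {
  if (is(loc, "Position")) return(loc@reference)
  if (is(loc, "Region")) return(loc@begin@reference)
  if (length(loc@members)) return(loc@members[[1]]@begin@reference)
  ""
}

#' Read feature records from a Turtle file
#'
#' @inheritParams readGff3
#' @param base base IRI the graph was emitted under
#' @return list with \code{records} and \code{report}
#' @export
readTurtleFeatures <- function(path, base = DEFAULT_BASE_IRI) {
  text <- readInputLines(path)
  records <- tryCatch(parseTriples(fromTurtle(text), base = base),
                      faldorError = function(e) e)
  if (is(records, "error"))
    return(list(records = list(),
                report = newReport(0L, 0L, 0L,
                  list(list(line = 0L, message = conditionMessage(records))))))
  list(records = records,
       report = newReport(length(records), length(records), 0L, list()))
}

## ---- writers --------------------------------------------------------------

## turn one location into GFF-style rows; fuzzy endpoints become their
## envelope (flagged), wrapped regions become one row per arc (flagged)
locationGffRows <- function(loc, ref) {
  if (is(loc, "RegionCollection")) {
    rows <- lapply(loc@members, locationGffRows, ref = ref)
    return(do.call(rbind, rows))
  }
  if (is(loc, "Position"))
    loc <- Region(loc, loc)
  fuzzy <- !is(loc@begin, "ExactPosition") || !is(loc@end, "ExactPosition")
  direct <- tryCatch(regionToGff(loc), faldorError = function(e) e)
  if (!is(direct, "error")) {
    return(data.frame(seqid = direct$seqid, start = direct$start,
                      end = direct$end, strand = direct$strand,
                      lossy = fuzzy, wrap = FALSE,
                      stringsAsFactors = FALSE))
  }
  ## mixed-strand endpoints carry information an interval row cannot hold;
  ## re-signal rather than silently flatten the strands away
  if (is.null(locationStrand(loc))) stop(direct)
  ## wrapped or fuzzy-beyond-direct: fall back to normalized arcs
  arcs <- normalizedArcs(loc, ref)
  s <- locationStrand(loc)
  sym <- if (is.null(s) || is.na(s)) "." else
    switch(s, forward = "+", reverse = "-", ".")
  data.frame(seqid = loc@begin@reference, start = arcs$start,
             end = arcs$end, strand = sym, lossy = fuzzy,
             wrap = nrow(arcs) > 1L, stringsAsFactors = FALSE)
}

writeGff3Records <- function(records, path, refs) {
  lines <- "##gff-version 3"
  warnings <- list()
  nOut <- 0L
  for (rec in records) {
    rows <- tryCatch({
      do.call(rbind, lapply(rec@locations, function(loc)
        locationGffRows(loc, refs[[locationReferenceId(loc)]])))
    }, error = function(e) e)
    if (is(rows, "error")) {
      warnings[[length(warnings) + 1L]] <-
        list(line = NA_integer_,
             message = sprintf("%s: %s", rec@featureId,
                               conditionMessage(rows)))
      next
    }
    attrs <- rec@attributes
    src <- if (!is.null(attrs$.gff_source)) attrs$.gff_source else "."
    score <- if (!is.null(attrs$.gff_score)) attrs$.gff_score else "."
    phase <- if (!is.null(attrs$.gff_phase)) attrs$.gff_phase else "."
    unknownStrand <- !is.null(attrs$.gff_strand_unknown)
    outAttrs <- attrs[!names(attrs) %in% GFF_RESERVED]
    outAttrs <- c(list(ID = rec@featureId), outAttrs[names(outAttrs) != "ID"])
    for (j in seq_len(nrow(rows))) {
      rowAttrs <- outAttrs
      if (rows$lossy[j]) {
        rowAttrs$lossy_fuzzy <- "1"
        warnings[[length(warnings) + 1L]] <-
          list(line = NA_integer_,
               message = sprintf("%s: fuzzy location exported as envelope",
                                 rec@featureId))
      }
      if (rows$wrap[j]) rowAttrs$origin_wrap <- "1"
      strandSym <- if (unknownStrand && rows$strand[j] == ".") "?"
                   else rows$strand[j]
      lines <- c(lines, paste(
        rows$seqid[j], src, rec@featureType, rows$start[j], rows$end[j],
        score, strandSym, phase, formatGffAttributes(rowAttrs),
        sep = "\t"))
    }
    if (nrow(rows) > 0L) nOut <- nOut + 1L
  }
  writeLines(lines, path)
  newReport(length(records), nOut, 0L, warnings)
}

writeBedRecords <- function(records, path, refs) {
  lines <- character()
  warnings <- list()
  nOut <- 0L
  for (rec in records) {
    converted <- FALSE
    for (loc in rec@locations) {
      rows <- tryCatch(
        locationGffRows(loc, refs[[locationReferenceId(loc)]]),
        error = function(e) e)
      if (is(rows, "error")) {
        warnings[[length(warnings) + 1L]] <-
          list(line = NA_integer_,
               message = sprintf("%s: %s", rec@featureId,
                                 conditionMessage(rows)))
        next
      }
      if (any(rows$lossy))
        warnings[[length(warnings) + 1L]] <-
          list(line = NA_integer_,
               message = sprintf("%s: fuzzy location exported as envelope",
                                 rec@featureId))
      score <- if (!is.null(rec@attributes$.bed_score))
        rec@attributes$.bed_score else "0"
      for (j in seq_len(nrow(rows))) {
        strandSym <- rows$strand[j]
        lines <- c(lines, paste(
          rows$seqid[j], rows$start[j] - 1L, rows$end[j], rec@featureId,
          score, if (strandSym %in% c("+", "-")) strandSym else ".",
          sep = "\t"))
      }
      if (nrow(rows) > 0L) converted <- TRUE
    }
    if (converted) nOut <- nOut + 1L
  }
  writeLines(lines, path)
  newReport(length(records), nOut, 0L, warnings)
}

writeFeatureTableRecords <- function(records, path, defaultRef, refs) {
  lines <- character()
  warnings <- list()
  nOut <- 0L
  for (rec in records) {
    converted <- FALSE
    for (loc in rec@locations) {
      ref <- refs[[locationReferenceId(loc)]]
      if (is(loc, "Region") && !is.null(ref))
        loc <- expandOriginJoin(loc, ref)
      s <- tryCatch(serializeInsdc(loc, defaultRef),
                    faldorError = function(e) e)
      if (is(s, "error")) {
        warnings[[length(warnings) + 1L]] <-
          list(line = NA_integer_,
               message = sprintf("%s: %s", rec@featureId,
                                 conditionMessage(s)))
        next
      }
      key <- substr(rec@featureType, 1, 15)
      lines <- c(lines, sprintf("     %-16s%s", key, s))
      quals <- rec@attributes
      if (!"gene" %in% names(quals) && !"locus_tag" %in% names(quals))
        quals <- c(list(label = rec@featureId), quals)
      for (k in names(quals))
        lines <- c(lines,
                   sprintf("                     /%s=\"%s\"", k,
                           as.character(quals[[k]])))
      converted <- TRUE
    }
    if (converted) nOut <- nOut + 1L
  }
  writeLines(lines, path)
  newReport(length(records), nOut, 0L, warnings)
}

#' Write feature records to a file
#'
#' @param records list of \code{FeatureRecord}s
#' @param path output path
#' @param format \code{"gff3"}, \code{"bed"}, \code{"turtle"} or
#'   \code{"insdc"}
#' @param refs named list of \code{ReferenceSequence}s (used to split
#'   origin-wrapping regions into arcs for interval formats)
#' @param defaultRef implicit reference for INSDC output
#' @param base base IRI for Turtle output
#' @return a \code{ConversionReport}; records not expressible in the target
#'   format appear as warnings, fuzzy locations exported to interval
#'   formats are flagged
#' @export
writeFeatures <- function(records, path,
                          format = c("gff3", "bed", "turtle", "insdc"),
                          refs = list(), defaultRef = "unnamed",
                          base = DEFAULT_BASE_IRI) {
  format <- match.arg(format)
  switch(format,
    gff3 = writeGff3Records(records, path, refs),
    bed = writeBedRecords(records, path, refs),
    insdc = writeFeatureTableRecords(records, path, defaultRef, refs),
    turtle = {
      writeLines(toTurtle(emitTriples(records, base = base)), path)
      newReport(length(records), length(records), 0L, list())
    })
}
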