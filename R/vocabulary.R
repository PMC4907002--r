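## Canonical registry of the ontology's terms.  Every IRI used by the RDF
## emitter, parser and Turtle serializer resolves through this registry;
## no other file contains a literal term IRI.
##
## The ontology defines 16 classes (12 dealing with positions, the region
## class and 3 region-collection classes), a handful of object properties,
## and exactly one datatype property (`position`, the 1-based integer
## offset).  Term names are case-sensitive: `position` is the datatype
## property, `Position` the class.
##
## Property names not fixed by prose (one-of membership, in-between
## neighbours, in-range bounds) follow the published vocabulary: the bounds
## of an InRangePosition reuse `begin`/`end`, one-of candidates hang off
## `possiblePosition`, and in-between neighbours use `after`/`before`.
## They are isolated here so a correction touches a single table.

.faldo <- new.env(parent = emptyenv())
.faldo$namespace <- "http://biohackathon.org/resource/faldo#"

#' Get or set the vocabulary namespace
#'
#' Defaults to the published FALDO namespace; configurable so that emitted
#' graphs can target a local namespace without network assumptions.
#'
#' @param value if given, the new namespace IRI prefix
#' @return the namespace IRI prefix (invisibly when setting)
#' @export
faldoNamespace <- function(value) {
  if (!missing(value)) {
    stopifnot(is.character(value), length(value) == 1L, nzchar(value))
    .faldo$namespace <- value
    return(invisible(value))
  }
  .faldo$namespace
}

## name -> parent classes (character(0) = root)
.classTable <- list(
  "Position"              = character(),
  "ExactPosition"         = "Position",
  "FuzzyPosition"         = "Position",
  "InBetweenPosition"     = "FuzzyPosition",
  "InRangePosition"       = "FuzzyPosition",
  "OneOfPosition"         = "FuzzyPosition",
  "StrandedPosition"      = "Position",
  "ForwardStrandPosition" = "StrandedPosition",
  "ReverseStrandPosition" = "StrandedPosition",
  "BothStrandsPosition"   = "StrandedPosition",
  "N-TerminalPosition"    = "ExactPosition",
  "C-TerminalPosition"    = "ExactPosition",
  "Region"                = character(),
  "CollectionOfRegions"   = character(),
  "ListOfRegions"         = "CollectionOfRegions",
  "BagOfRegions"          = "CollectionOfRegions"
)

.objectProperties <- c("location", "begin", "end", "reference",
                       "after", "before", "possiblePosition")

.datatypeProperties <- c("position")

#' The canonical class registry
#'
#' @return a data.frame with columns \code{name}, \code{iri} and
#'   \code{parents} (comma-separated), one row per class, sorted by name.
#'   Exactly 16 classes.
#' @examples
#' nrow(faldoClasses())  # 16
#' @export
faldoClasses <- function() {
  ns <- faldoNamespace()
  nm <- sort(names(.classTable))
  data.frame(
    name = nm,
    iri = paste0(ns, nm),
    parents = vapply(.classTable[nm], paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  )
}

#' Parent classes of a vocabulary class
#' @param name class name
#' @return character vector of direct parents (empty for roots)
#' @export
faldoParents <- function(name) {
  if (!name %in% names(.classTable))
    stopFaldor("UnknownTerm", sprintf("unknown class: %s", name))
  .classTable[[name]]
}

#' All ancestors (transitive parents) of a vocabulary class
#' @inheritParams faldoParents
#' @export
faldoAncestors <- function(name) {
  out <- character()
  todo <- faldoParents(name)
  while (length(todo)) {
    p <- todo[[1]]; todo <- todo[-1]
    if (!p %in% out) {
      out <- c(out, p)
      todo <- c(todo, faldoParents(p))
    }
  }
  out
}

#' Object and datatype properties of the vocabulary
#'
#' @return a data.frame with columns \code{name}, \code{iri}, \code{kind}
#'   (\code{"object"} or \code{"datatype"}).  Exactly one datatype property.
#' @export
faldoProperties <- function() {
  ns <- faldoNamespace()
  nm <- c(sort(.objectProperties), sort(.datatypeProperties))
  data.frame(
    name = nm,
    iri = paste0(ns, nm),
    kind = c(rep("object", length(.objectProperties)),
             rep("datatype", length(.datatypeProperties))),
    stringsAsFactors = FALSE
  )
}

knownTermNames <- function() {
  c(names(.classTable), .objectProperties, .datatypeProperties)
}

#' Resolve a term name to its IRI
#'
#' @param name a class or property name (case-sensitive)
#' @return character(1) IRI
#' @examples
#' faldoIRI("ExactPosition")
#' @export
faldoIRI <- function(name) {
  if (!all(name %in% knownTermNames()))
    stopFaldor("UnknownTerm",
      sprintf("unknown term(s): %s",
              paste(setdiff(name, knownTermNames()), collapse = ", ")))
  paste0(faldoNamespace(), name)
}

#' Are two term names distinct terms?
#'
#' Term names are case-sensitive, so \code{"position"} (the datatype
#' property) and \code{"Position"} (the class) are distinct.
#'
#' @param nameA,nameB term names
#' @return logical(1): TRUE iff the names denote different terms
#' @export
isCaseDistinct <- function(nameA, nameB) {
  known <- knownTermNames()
  if (!nameA %in% known)
    stopFaldor("UnknownTerm", sprintf("unknown term: %s", nameA))
  if (!nameB %in% known)
    stopFaldor("UnknownTerm", sprintf("unknown term: %s", nameB))
  !identical(nameA, nameB)
}

## model class -> vocabulary class name(s) for a position object
positionClassNames <- function(p) {
  base <- if (is(p, "NTerminalPosition")) "N-TerminalPosition"
    else if (is(p, "CTerminalPosition")) "C-TerminalPosition"
    else if (is(p, "ExactPosition")) "ExactPosition"
    else if (is(p, "InRangePosition")) "InRangePosition"
    else if (is(p, "OneOfPosition")) "OneOfPosition"
    else if (is(p, "InBetweenPosition")) "InBetweenPosition"
    else "Position"
  strandCls <- if (is.na(p@strand)) character()
    else switch(p@strand,
      forward = "ForwardStrandPosition",
      reverse = "ReverseStrandPosition",
      both = "BothStrandsPosition")
  c(base, strandCls)
}

#' Export the vocabulary as a Turtle document
#'
#' Writes the class hierarchy and property declarations as RDF Schema
#' triples.
#'
#' @param path file to write, or \code{NULL} to return the text
#' @return the Turtle text, invisibly when written to a file
#' @export
writeVocabulary <- function(path = NULL) {
  ns <- faldoNamespace()
  cls <- faldoClasses()
  props <- faldoProperties()
  g <- emptyGraph()
  rdfType <- rdfIRI("type")
  for (i in seq_len(nrow(cls))) {
    g <- addTriple(g, cls$iri[i], rdfType,
                   "http://www.w3.org/2002/07/owl#Class")
    for (p in .classTable[[cls$name[i]]])
      g <- addTriple(g, cls$iri[i],
                     "http://www.w3.org/2000/01/rdf-schema#subClassOf",
                     paste0(ns, p))
  }
  for (i in seq_len(nrow(props))) {
    kind <- if (props$kind[i] == "object")
      "http://www.w3.org/2002/07/owl#ObjectProperty"
    else
      "http://www.w3.org/2002/07/owl#DatatypeProperty"
    g <- addTriple(g, props$iri[i], rdfType, kind)
  }
  txt <- toTurtle(g)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
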