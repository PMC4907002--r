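## Feature records <-> triple graphs.
##
## Emission follows the ontology's shapes: a feature node links to its
## location node(s); a region node carries begin/end position nodes; every
## position node is typed with its position class plus a strand class when a
## strand claim exists, and carries its integer offset (`position`) and its
## reference sequence (`reference`).  Strand typing appears only on position
## nodes, never on regions.
##
## Blank nodes are never emitted.  Position, region and collection nodes get
## deterministic skolem IRIs built from their structural content key, so the
## same position content always yields the same node label: graphs diff
## cleanly, and emission itself already pre-merges identical positions.

DEFAULT_BASE_IRI <- "http://example.org/"

## record -> primary sequence link used by the reference-materialization
## rule (the chain axiom's anchor); kept under the package's record
## vocabulary, configurable per call
DEFAULT_SEQUENCE_PREDICATE <- "http://example.org/vocab/sequence"

encodeLabel <- function(x) {
  utils::URLencode(x, reserved = TRUE)
}

decodeLabel <- function(x) {
  utils::URLdecode(x)
}

looksLikeIRI <- function(x) {
  grepl("^[A-Za-z][A-Za-z0-9+.-]*://", x) ||
    grepl("^(urn|tag|mailto|_):", x)
}

iriFor <- function(id, kind, base) {
  if (looksLikeIRI(id)) id else paste0(base, kind, "/", encodeLabel(id))
}

idFromIRI <- function(iri, kind, base) {
  prefix <- paste0(base, kind, "/")
  if (startsWith(iri, prefix))
    decodeLabel(substr(iri, nchar(prefix) + 1L, nchar(iri)))
  else iri
}

positionNodeIRI <- function(p, base) {
  paste0(base, "position/", encodeLabel(positionKey(p)))
}

regionNodeIRI <- function(r, base) {
  paste0(base, "region/", encodeLabel(regionKey(r)))
}

## ---- emission -------------------------------------------------------------

emitPosition <- function(acc, p, base) {
  node <- positionNodeIRI(p, base)
  typePred <- rdfIRI("type")
  for (cls in positionClassNames(p))
    accAdd(acc, node, typePred, faldoIRI(cls))
  refPred <- faldoIRI("reference")
  if (nzchar(p@reference))
    accAdd(acc, node, refPred, iriFor(p@reference, "sequence", base))
  if (is(p, "ExactPosition")) {
    accAddInt(acc, node, faldoIRI("position"), p@coordinate)
  } else if (is(p, "InRangePosition")) {
    if (!is.null(p@lowBound))
      accAdd(acc, node, faldoIRI("begin"), emitPosition(acc, p@lowBound, base))
    if (!is.null(p@highBound))
      accAdd(acc, node, faldoIRI("end"), emitPosition(acc, p@highBound, base))
  } else if (is(p, "OneOfPosition")) {
    for (o in p@options)
      accAdd(acc, node, faldoIRI("possiblePosition"),
             emitPosition(acc, o, base))
  } else if (is(p, "InBetweenPosition")) {
    accAdd(acc, node, faldoIRI("after"), emitPosition(acc, p@after, base))
    accAdd(acc, node, faldoIRI("before"), emitPosition(acc, p@before, base))
  }
  node
}

emitRegion <- function(acc, r, base) {
  node <- regionNodeIRI(r, base)
  accAdd(acc, node, rdfIRI("type"), faldoIRI("Region"))
  accAdd(acc, node, faldoIRI("begin"), emitPosition(acc, r@begin, base))
  accAdd(acc, node, faldoIRI("end"), emitPosition(acc, r@end, base))
  node
}

emitCollection <- function(acc, col, base) {
  key <- locationKey(col)
  node <- paste0(base, "collection/", encodeLabel(key))
  cls <- switch(col@kind, list = "ListOfRegions", bag = "BagOfRegions",
                "CollectionOfRegions")
  accAdd(acc, node, rdfIRI("type"), faldoIRI(cls))
  memberNodes <- vapply(col@members, function(m) emitRegion(acc, m, base),
                        character(1))
  if (col@kind == "list") {
    ## ordered: an rdf:first/rdf:rest chain hanging off the collection node
    cell <- node
    for (i in seq_along(memberNodes)) {
      accAdd(acc, cell, rdfIRI("first"), memberNodes[i])
      nxt <- if (i == length(memberNodes)) rdfIRI("nil")
             else paste0(node, "/cell/", i + 1L)
      accAdd(acc, cell, rdfIRI("rest"), nxt)
      cell <- nxt
    }
  } else {
    for (m in memberNodes)
      accAdd(acc, node, rdfsIRI("member"), m)
  }
  node
}

#' Emit feature records as a triple graph
#'
#' @param features list of \code{FeatureRecord}s
#' @param base base IRI under which plain (non-IRI) identifiers and skolem
#'   node labels are minted
#' @return a \code{TripleGraph}
#' @examples
#' chey <- FeatureRecord("cheY",
#'   parseInsdc("complement(1965072..1965461)", "NC_000913.2"),
#'   featureType = "gene")
#' g <- emitTriples(list(chey))
#' @export
emitTriples <- function(features, base = DEFAULT_BASE_IRI) {
  if (is(features, "FeatureRecord")) features <- list(features)
  acc <- newAcc()
  typePred <- rdfIRI("type")
  locPred <- faldoIRI("location")
  for (f in features) {
    fnode <- iriFor(f@featureId, "feature", base)
    accAdd(acc, fnode, typePred, iriFor(f@featureType, "type", base))
    for (loc in f@locations) {
      lnode <- if (is(loc, "Region")) emitRegion(acc, loc, base)
        else if (is(loc, "RegionCollection")) emitCollection(acc, loc, base)
        else emitPosition(acc, loc, base)
      accAdd(acc, fnode, locPred, lnode)
    }
    for (key in names(f@attributes))
      accAddString(acc, fnode, paste0(base, "attribute/", encodeLabel(key)),
                   as.character(f@attributes[[key]]))
  }
  accGraph(acc)
}

## ---- parsing --------------------------------------------------------------

## fast lookup tables over a graph
graphIndex <- function(g) {
  df <- canonicalTriples(g@triples)
  idx <- new.env(parent = emptyenv())
  idx$df <- df
  key <- paste0(df$subject, "\r", df$predicate)
  idx$bySP <- split(seq_len(nrow(df)), key)
  idx
}

idxObjects <- function(idx, subject, predicate, kind = NULL) {
  rows <- idx$bySP[[paste0(subject, "\r", predicate)]]
  if (is.null(rows)) return(character())
  if (!is.null(kind))
    rows <- rows[idx$df$objectKind[rows] == kind]
  idx$df$object[rows]
}

positionClassIRIs <- function() {
  faldoIRI(c("Position", "ExactPosition", "FuzzyPosition",
             "InBetweenPosition", "InRangePosition", "OneOfPosition",
             "StrandedPosition", "ForwardStrandPosition",
             "ReverseStrandPosition", "BothStrandsPosition",
             "N-TerminalPosition", "C-TerminalPosition"))
}

strandFromTypes <- function(types) {
  claims <- character()
  if (faldoIRI("ForwardStrandPosition") %in% types)
    claims <- c(claims, "forward")
  if (faldoIRI("ReverseStrandPosition") %in% types)
    claims <- c(claims, "reverse")
  if (faldoIRI("BothStrandsPosition") %in% types)
    claims <- c(claims, "both")
  if (length(claims) > 1L)
    stopFaldor("ContradictoryStrand",
      sprintf("node carries contradictory strand classes: %s",
              paste(claims, collapse = ", ")))
  if (length(claims) == 0L) NA_character_ else claims
}

parsePositionNode <- function(idx, node, base) {
  typePred <- rdfIRI("type")
  types <- idxObjects(idx, node, typePred)
  strand <- strandFromTypes(types)
  refs <- idxObjects(idx, node, faldoIRI("reference"))
  ref <- if (length(refs)) idFromIRI(refs[1], "sequence", base) else ""
  isa <- function(cls) faldoIRI(cls) %in% types
  if (isa("ExactPosition") || isa("N-TerminalPosition") ||
      isa("C-TerminalPosition")) {
    lit <- idxObjects(idx, node, faldoIRI("position"), kind = "literal")
    if (length(lit) == 0L)
      stopFaldor("DanglingPosition",
        sprintf("exact position node %s has no position literal", node))
    if (length(unique(lit)) > 1L)
      stopFaldor("KeyConflict",
        sprintf("node %s carries multiple position literals", node))
    coord <- suppressWarnings(as.integer(lit[1]))
    if (is.na(coord))
      stopFaldor("TypeError",
        sprintf("non-integer position literal on %s: %s", node, lit[1]))
    if (!nzchar(ref))
      stopFaldor("DanglingPosition",
        sprintf("position node %s lacks a reference", node))
    if (isa("N-TerminalPosition"))
      return(new("NTerminalPosition", coordinate = coord, reference = ref,
                 strand = strand))
    if (isa("C-TerminalPosition"))
      return(new("CTerminalPosition", coordinate = coord, reference = ref,
                 strand = strand))
    return(new("ExactPosition", coordinate = coord, reference = ref,
               strand = strand))
  }
  if (isa("InRangePosition")) {
    lowN <- idxObjects(idx, node, faldoIRI("begin"), kind = "iri")
    highN <- idxObjects(idx, node, faldoIRI("end"), kind = "iri")
    lo <- if (length(lowN)) parsePositionNode(idx, lowN[1], base) else NULL
    hi <- if (length(highN)) parsePositionNode(idx, highN[1], base) else NULL
    if (!nzchar(ref))
      stopFaldor("DanglingPosition",
        sprintf("position node %s lacks a reference", node))
    return(new("InRangePosition", lowBound = lo, highBound = hi,
               reference = ref, strand = strand))
  }
  if (isa("OneOfPosition")) {
    opts <- idxObjects(idx, node, faldoIRI("possiblePosition"), kind = "iri")
    if (!nzchar(ref))
      stopFaldor("DanglingPosition",
        sprintf("position node %s lacks a reference", node))
    opts <- lapply(sort(opts), parsePositionNode, idx = idx, base = base)
    return(new("OneOfPosition", options = opts, reference = ref,
               strand = strand))
  }
  if (isa("InBetweenPosition")) {
    aN <- idxObjects(idx, node, faldoIRI("after"), kind = "iri")
    bN <- idxObjects(idx, node, faldoIRI("before"), kind = "iri")
    if (length(aN) == 0L || length(bN) == 0L)
      stopFaldor("DanglingPosition",
        sprintf("in-between node %s lacks after/before", node))
    a <- parsePositionNode(idx, aN[1], base)
    b <- parsePositionNode(idx, bN[1], base)
    return(new("InBetweenPosition", after = a, before = b,
               reference = if (nzchar(ref)) ref else a@reference,
               strand = strand))
  }
  stopFaldor("DanglingPosition",
    sprintf("node %s is not typed as a known position class", node))
}

parseRegionNode <- function(idx, node, base) {
  beginN <- idxObjects(idx, node, faldoIRI("begin"), kind = "iri")
  endN <- idxObjects(idx, node, faldoIRI("end"), kind = "iri")
  if (length(beginN) == 0L || length(endN) == 0L)
    stopFaldor("DanglingPosition",
      sprintf("region node %s lacks begin or end", node))
  Region(parsePositionNode(idx, beginN[1], base),
         parsePositionNode(idx, endN[1], base))
}

parseCollectionNode <- function(idx, node, base, types) {
  if (faldoIRI("ListOfRegions") %in% types) {
    members <- list()
    cell <- node
    nil <- rdfIRI("nil")
    while (!identical(cell, nil)) {
      first <- idxObjects(idx, cell, rdfIRI("first"), kind = "iri")
      rest <- idxObjects(idx, cell, rdfIRI("rest"), kind = "iri")
      if (length(first) == 0L || length(rest) == 0L)
        stopFaldor("DanglingPosition",
          sprintf("broken list structure at %s", cell))
      members[[length(members) + 1L]] <- parseRegionNode(idx, first[1], base)
      cell <- rest[1]
    }
    return(RegionCollection(members, kind = "list"))
  }
  memberN <- sort(idxObjects(idx, node, rdfsIRI("member"), kind = "iri"))
  members <- lapply(memberN, parseRegionNode, idx = idx, base = base)
  kind <- if (faldoIRI("BagOfRegions") %in% types) "bag" else "collection"
  RegionCollection(members, kind = kind)
}

#' Parse feature records out of a triple graph
#'
#' Inverse of \code{\link{emitTriples}} up to node renaming: every subject
#' with a \code{location} link becomes a \code{FeatureRecord}.
#'
#' @param g a \code{TripleGraph} using the registry's namespace
#' @param base base IRI used when the graph was emitted (to recover plain
#'   identifiers)
#' @return list of \code{FeatureRecord}s, sorted by feature identifier
#' @export
parseTriples <- function(g, base = DEFAULT_BASE_IRI) {
  idx <- graphIndex(g)
  df <- idx$df
  locPred <- faldoIRI("location")
  featNodes <- sort(unique(df$subject[df$predicate == locPred]))
  typePred <- rdfIRI("type")
  attrPrefix <- paste0(base, "attribute/")
  lapply(featNodes, function(fnode) {
    locNodes <- sort(idxObjects(idx, fnode, locPred, kind = "iri"))
    locs <- lapply(locNodes, function(lnode) {
      types <- idxObjects(idx, lnode, typePred)
      if (any(faldoIRI(c("ListOfRegions", "BagOfRegions",
                         "CollectionOfRegions")) %in% types))
        parseCollectionNode(idx, lnode, base, types)
      else if (faldoIRI("Region") %in% types ||
               length(idxObjects(idx, lnode, faldoIRI("begin"))) > 0L)
        parseRegionNode(idx, lnode, base)
      else
        parsePositionNode(idx, lnode, base)
    })
    ftypes <- idxObjects(idx, fnode, typePred)
    ftypes <- ftypes[!ftypes %in% faldoIRI(faldoClasses()$name)]
    ftype <- if (length(ftypes)) idFromIRI(sort(ftypes)[1], "type", base)
             else "region"
    arows <- df$subject == fnode & startsWith(df$predicate, attrPrefix)
    attrs <- list()
    if (any(arows)) {
      keys <- decodeLabel(substring(df$predicate[arows],
                                    nchar(attrPrefix) + 1L))
      vals <- df$object[arows]
      o <- order(keys)
      attrs <- as.list(vals[o])
      names(attrs) <- keys[o]
    }
    FeatureRecord(idFromIRI(fnode, "feature", base), locs,
                  featureType = ftype, attributes = attrs)
  })
}

## ---- reasoning rule 1: property-chain reference materialization -----------

#' A hop in a materialization chain
#'
#' @param predicates character vector of predicate IRIs usable for this hop
#' @param star if TRUE the hop is a reflexive-transitive closure (zero or
#'   more steps along any of the predicates)
#' @return a chain-hop description
#' @export
chainHop <- function(predicates, star = FALSE) {
  structure(list(predicates = predicates, star = star), class = "chainHop")
}

#' The default reference-materialization chain
#'
#' From a record node: one \code{location} hop, then a closure over the
#' structural predicates that lead from a location node to every position
#' node inside it (list cells, collection membership, region endpoints,
#' fuzzy-position bounds and neighbours).
#'
#' @return list of \code{\link{chainHop}}s
#' @export
defaultReferenceChain <- function() {
  list(
    chainHop(faldoIRI("location")),
    chainHop(c(rdfIRI("first"), rdfIRI("rest"), rdfsIRI("member"),
               faldoIRI("begin"), faldoIRI("end"), faldoIRI("after"),
               faldoIRI("before"), faldoIRI("possiblePosition")),
             star = TRUE)
  )
}

#' Materialize inferable reference triples
#'
#' Implements the property-chain rule procedurally: every record node that
#' declares a primary sequence transfers that sequence as the
#' \code{reference} of every position node reachable through the chain,
#' unless the position already has a reference.  Idempotent; never removes
#' triples.
#'
#' @param g a \code{TripleGraph}
#' @param chain list of \code{\link{chainHop}}s (default
#'   \code{\link{defaultReferenceChain}()})
#' @param primary predicate IRI linking a record node to its primary
#'   sequence
#' @return the augmented \code{TripleGraph}
#' @export
materializeReferences <- function(g, chain = defaultReferenceChain(),
                                  primary = DEFAULT_SEQUENCE_PREDICATE) {
  stopifnot(length(chain) >= 1L)
  idx <- graphIndex(g)
  df <- idx$df
  records <- unique(df$subject[df$predicate == primary])
  if (length(records) == 0L) return(g)
  posClasses <- positionClassIRIs()
  typePred <- rdfIRI("type")
  refPred <- faldoIRI("reference")
  typed <- unique(df$subject[df$predicate == typePred &
                             df$object %in% posClasses])
  hasRef <- unique(df$subject[df$predicate == refPred])
  acc <- newAcc()
  for (r in records) {
    seqs <- idxObjects(idx, r, primary, kind = "iri")
    frontier <- r
    for (hop in chain) {
      if (hop$star) {
        seen <- frontier
        todo <- frontier
        while (length(todo)) {
          nxt <- unique(unlist(lapply(todo, function(node)
            unlist(lapply(hop$predicates, function(p)
              idxObjects(idx, node, p, kind = "iri"))))))
          todo <- setdiff(nxt, seen)
          seen <- union(seen, todo)
        }
        frontier <- seen
      } else {
        frontier <- unique(unlist(lapply(frontier, function(node)
          unlist(lapply(hop$predicates, function(p)
            idxObjects(idx, node, p, kind = "iri"))))))
      }
      if (length(frontier) == 0L) break
    }
    targets <- setdiff(intersect(frontier, typed), hasRef)
    for (s in seqs)
      for (p in targets)
        accAdd(acc, p, refPred, s)
  }
  if (acc$n == 0L) return(finalizeGraph(g))
  TripleGraph(rbind(df, accGraph(acc)@triples))
}

## ---- reasoning rule 2: hasKey identity merge ------------------------------

## representative of each reference under owl:sameAs closure
sameAsRepresentatives <- function(df) {
  sameAs <- df[df$predicate == owlIRI("sameAs") & df$objectKind == "iri", ,
               drop = FALSE]
  nodes <- unique(c(sameAs$subject, sameAs$object))
  rep <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (rep[[x]] != x) x <- rep[[x]]
    x
  }
  for (i in seq_len(nrow(sameAs))) {
    a <- find(sameAs$subject[i]); b <- find(sameAs$object[i])
    if (a != b) {
      lo <- min(a, b); hi <- max(a, b)
      rep[[hi]] <- lo
    }
  }
  vapply(nodes, find, character(1))
}

#' Merge exact positions by their identity key
#'
#' Two exact positions are the same position when they carry the same
#' integer offset and the same reference sequence (references equated by
#' \code{owl:sameAs} count as the same) and make the same strand claim.
#' All nodes sharing a key collapse to one node (the lexicographically
#' smallest label), with every statement rewritten; idempotent and
#' order-independent, and the statement count never increases.
#'
#' @param g a \code{TripleGraph}
#' @return the merged \code{TripleGraph}
#' @export
mergeByKey <- function(g) {
  df <- canonicalTriples(g@triples)
  typePred <- rdfIRI("type")
  exactCls <- faldoIRI(c("ExactPosition", "N-TerminalPosition",
                         "C-TerminalPosition"))
  exactNodes <- unique(df$subject[df$predicate == typePred &
                                  df$object %in% exactCls])
  if (length(exactNodes) == 0L) return(TripleGraph(df))
  reps <- sameAsRepresentatives(df)
  refRep <- function(iri) {
    if (iri %in% names(reps)) reps[[iri]] else iri
  }
  posPred <- faldoIRI("position")
  refPred <- faldoIRI("reference")
  strandCls <- faldoIRI(c("ForwardStrandPosition", "ReverseStrandPosition",
                          "BothStrandsPosition"))
  idx <- graphIndex(TripleGraph(df))
  keys <- vapply(exactNodes, function(node) {
    lits <- unique(idxObjects(idx, node, posPred, kind = "literal"))
    if (length(lits) > 1L)
      stopFaldor("KeyConflict",
        sprintf("node %s carries %d different position values", node,
                length(lits)))
    if (length(lits) == 0L) return(NA_character_)
    refs <- unique(vapply(
      idxObjects(idx, node, refPred, kind = "iri"), refRep, character(1),
      USE.NAMES = FALSE))
    if (length(refs) != 1L) return(NA_character_)
    strands <- sort(intersect(idxObjects(idx, node, typePred), strandCls))
    paste(lits, refs, paste(strands, collapse = "|"), sep = "\r")
  }, character(1))
  ok <- !is.na(keys)
  mapping <- character()
  for (key in unique(keys[ok])) {
    members <- sort(exactNodes[ok & keys == key])
    if (length(members) > 1L)
      mapping[members[-1L]] <- members[1L]
  }
  if (length(mapping) == 0L) return(TripleGraph(df))
  remap <- function(x) {
    hit <- x %in% names(mapping)
    x[hit] <- mapping[x[hit]]
    x
  }
  df$subject <- remap(df$subject)
  iriObj <- df$objectKind == "iri"
  df$object[iriObj] <- remap(df$object[iriObj])
  TripleGraph(df)
}
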