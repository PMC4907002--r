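## Profile-based validation.
##
## Validation is an application concern, not a format concern: the model
## admits locations (multi-reference regions, opposite-strand endpoints)
## that specific databases refuse.  The core profile checks structural
## sanity every consumer needs; the insdc profile adds the rule that a
## region's endpoints share one reference sequence; the uniprot profile
## adds the rule that every position is described on a designated
## canonical sequence.  core is a subset of both, and violation lists are
## deterministic for a given input.

coreRules <- c("coordinate-positive", "region-endpoints",
               "strand-contradiction", "single-coordinate")

#' Validation profiles
#'
#' @return named list mapping profile name to its rule identifiers
#' @export
validationProfiles <- function() {
  list(
    core = coreRules,
    insdc = c(coreRules, "same-reference"),
    uniprot = c(coreRules, "canonical-reference")
  )
}

violation <- function(ruleId, subject, message, severity = "error") {
  data.frame(ruleId = ruleId, subject = subject, message = message,
             severity = severity, stringsAsFactors = FALSE)
}

emptyViolations <- function() {
  data.frame(ruleId = character(), subject = character(),
             message = character(), severity = character(),
             stringsAsFactors = FALSE)
}

## all position objects inside a location, for structural checks
allPositions <- function(loc) {
  if (is(loc, "Region"))
    return(c(allPositions(loc@begin), allPositions(loc@end)))
  if (is(loc, "RegionCollection"))
    return(unlist(lapply(loc@members, allPositions), recursive = FALSE))
  subs <- list()
  if (is(loc, "InRangePosition")) {
    if (!is.null(loc@lowBound)) subs <- c(subs, allPositions(loc@lowBound))
    if (!is.null(loc@highBound)) subs <- c(subs, allPositions(loc@highBound))
  } else if (is(loc, "OneOfPosition")) {
    subs <- unlist(lapply(loc@options, allPositions), recursive = FALSE)
  } else if (is(loc, "InBetweenPosition")) {
    subs <- c(allPositions(loc@after), allPositions(loc@before))
  }
  c(list(loc), subs)
}

allRegions <- function(loc) {
  if (is(loc, "Region")) return(list(loc))
  if (is(loc, "RegionCollection"))
    return(unlist(lapply(loc@members, allRegions), recursive = FALSE))
  list()
}

validateRecord <- function(rec, rules, canonical) {
  out <- list()
  add <- function(v) out[[length(out) + 1L]] <<- v
  fid <- rec@featureId
  for (loc in rec@locations) {
    positions <- allPositions(loc)
    regions <- allRegions(loc)
    if ("coordinate-positive" %in% rules) {
      for (p in positions) {
        if (is(p, "ExactPosition") && p@coordinate < 1L)
          add(violation("coordinate-positive", fid,
            sprintf("coordinate %d is below 1", p@coordinate)))
      }
    }
    if ("single-coordinate" %in% rules) {
      ## an S4 ExactPosition cannot structurally carry two coordinates, but
      ## a length != 1 slot (constructed by force) is the same defect
      for (p in positions) {
        if (is(p, "ExactPosition") && length(p@coordinate) != 1L)
          add(violation("single-coordinate", fid,
            "exact position must carry exactly one coordinate"))
      }
    }
    if ("same-reference" %in% rules) {
      for (r in regions) {
        if (!identical(r@begin@reference, r@end@reference))
          add(violation("same-reference", fid,
            sprintf("region endpoints on %s and %s", r@begin@reference,
                    r@end@reference)))
      }
    }
    if ("canonical-reference" %in% rules) {
      for (p in positions) {
        if (nzchar(p@reference) && !identical(p@reference, canonical))
          add(violation("canonical-reference", fid,
            sprintf("position on %s, not the canonical sequence %s",
                    p@reference, if (is.null(canonical)) "<unset>"
                    else canonical)))
      }
    }
  }
  out
}

validateGraphNodes <- function(g, rules, canonical = NULL) {
  out <- list()
  add <- function(v) out[[length(out) + 1L]] <<- v
  df <- canonicalTriples(g@triples)
  typePred <- rdfIRI("type")
  if ("strand-contradiction" %in% rules) {
    fwd <- df$subject[df$predicate == typePred &
                      df$object == faldoIRI("ForwardStrandPosition")]
    rev <- df$subject[df$predicate == typePred &
                      df$object == faldoIRI("ReverseStrandPosition")]
    for (node in sort(intersect(fwd, rev)))
      add(violation("strand-contradiction", node,
        "node typed both forward- and reverse-stranded"))
  }
  if ("single-coordinate" %in% rules) {
    posPred <- faldoIRI("position")
    lits <- df[df$predicate == posPred, , drop = FALSE]
    counts <- table(lits$subject[!duplicated(paste(lits$subject,
                                                   lits$object))])
    for (node in sort(names(counts)[counts > 1L]))
      add(violation("single-coordinate", node,
        "exact position node carries more than one coordinate"))
  }
  if ("region-endpoints" %in% rules) {
    regions <- df$subject[df$predicate == typePred &
                          df$object == faldoIRI("Region")]
    hasBegin <- df$subject[df$predicate == faldoIRI("begin")]
    hasEnd <- df$subject[df$predicate == faldoIRI("end")]
    for (node in sort(setdiff(regions, intersect(hasBegin, hasEnd))))
      add(violation("region-endpoints", node,
        "region lacks a begin or end position"))
  }
  refPred <- faldoIRI("reference")
  refOf <- function(node) {
    unique(df$object[df$subject == node & df$predicate == refPred])
  }
  if ("same-reference" %in% rules) {
    regions <- df$subject[df$predicate == typePred &
                          df$object == faldoIRI("Region")]
    for (node in sort(regions)) {
      ends <- c(df$object[df$subject == node &
                          df$predicate == faldoIRI("begin")],
                df$object[df$subject == node &
                          df$predicate == faldoIRI("end")])
      refs <- unique(unlist(lapply(ends, refOf)))
      if (length(refs) > 1L)
        add(violation("same-reference", node,
          sprintf("region endpoints on %d different references",
                  length(refs))))
    }
  }
  if ("canonical-reference" %in% rules && !is.null(canonical)) {
    posNodes <- unique(df$subject[df$predicate == refPred])
    for (node in sort(posNodes)) {
      refs <- refOf(node)
      ids <- vapply(refs, idFromIRI, character(1), kind = "sequence",
                    base = DEFAULT_BASE_IRI, USE.NAMES = FALSE)
      if (!all(refs == canonical | ids == canonical))
        add(violation("canonical-reference", node,
          sprintf("position not on the canonical sequence %s", canonical)))
    }
  }
  out
}

#' Validate feature records or a triple graph against a profile
#'
#' Core rules: coordinates at least 1; regions carry both endpoints; no
#' node claims both the forward and the reverse strand; an exact position
#' carries exactly one coordinate.  The insdc profile adds the rule that
#' region endpoints share one reference; the uniprot profile requires all
#' positions to sit on the designated canonical sequence.
#'
#' Violations are monotone in the profile: everything core flags is also
#' flagged by insdc and uniprot on the same input.
#'
#' @param data list of \code{FeatureRecord}s or a \code{TripleGraph}
#' @param profile \code{"core"}, \code{"insdc"} or \code{"uniprot"}
#' @param canonical canonical sequence identifier (required meaningfully
#'   by the uniprot profile)
#' @return data.frame of violations (\code{ruleId}, \code{subject},
#'   \code{message}, \code{severity}); zero rows when valid
#' @examples
#' chey <- FeatureRecord("cheY",
#'   parseInsdc("complement(1965072..1965461)", "NC_000913.2"))
#' nrow(validateFeatures(list(chey), profile = "insdc"))  # 0
#' @export
validateFeatures <- function(data, profile = "core", canonical = NULL) {
  profiles <- validationProfiles()
  if (!profile %in% names(profiles))
    stopFaldor("UnknownProfile", sprintf("unknown profile: %s", profile))
  rules <- profiles[[profile]]
  out <- if (is(data, "TripleGraph")) {
    validateGraphNodes(data, rules, canonical)
  } else {
    if (is(data, "FeatureRecord")) data <- list(data)
    ## structural strand contradictions cannot arise in the S4 model (one
    ## strand slot); they are a graph-level concern
    unlist(lapply(data, validateRecord, rules = rules,
                  canonical = canonical), recursive = FALSE)
  }
  if (length(out) == 0L) return(emptyViolations())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
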