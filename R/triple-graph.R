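## Abstract triple graph with a deterministic Turtle serialization.
##
## Triples are kept in a data.frame with set semantics (duplicates collapse
## on canonicalization).  Nodes are IRIs; blank nodes are avoided by the
## emitter (positions and regions get deterministic skolem IRIs derived from
## their content), but "_:" labels surviving from parsed input are carried
## through unchanged.

RDF_NS  <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
RDFS_NS <- "http://www.w3.org/2000/01/rdf-schema#"
XSD_NS  <- "http://www.w3.org/2001/XMLSchema#"
OWL_NS  <- "http://www.w3.org/2002/07/owl#"

rdfIRI <- function(name) paste0(RDF_NS, name)
rdfsIRI <- function(name) paste0(RDFS_NS, name)
xsdIRI <- function(name) paste0(XSD_NS, name)
owlIRI <- function(name) paste0(OWL_NS, name)

#' A set of RDF triples
#'
#' @slot triples data.frame with columns \code{subject}, \code{predicate},
#'   \code{object}, \code{objectKind} (\code{"iri"} or \code{"literal"}) and
#'   \code{datatype} (IRI or \code{NA}); duplicate statements collapse.
#' @aliases TripleGraph-class
#' @exportClass TripleGraph
setClass("TripleGraph", representation(triples = "data.frame"))

emptyTriples <- function() {
  data.frame(subject = character(), predicate = character(),
             object = character(), objectKind = character(),
             datatype = character(), stringsAsFactors = FALSE)
}

canonicalTriples <- function(df) {
  df <- unique(df)
  o <- order(df$subject, df$predicate, df$objectKind, df$object,
             method = "radix")
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  df
}

setValidity("TripleGraph", function(object) {
  df <- object@triples
  need <- c("subject", "predicate", "object", "objectKind", "datatype")
  if (!all(need %in% names(df)))
    return("triples must have subject/predicate/object/objectKind/datatype")
  if (nrow(df) && !all(df$objectKind %in% c("iri", "literal")))
    return("objectKind must be 'iri' or 'literal'")
  posPred <- paste0(faldoNamespace(), "position")
  pos <- df$predicate == posPred
  if (any(pos)) {
    v <- suppressWarnings(as.numeric(df$object[pos]))
    if (any(is.na(v)) || any(v < 1) || any(v != floor(v)))
      return("every position literal must be a positive integer")
  }
  TRUE
})

#' Create an empty triple graph
#' @return a \code{TripleGraph}
#' @export
emptyGraph <- function() {
  new("TripleGraph", triples = emptyTriples())
}

#' Create a triple graph from a statement data.frame
#' @param triples data.frame as in the \code{TripleGraph} slot; the
#'   \code{objectKind}/\code{datatype} columns default to IRI objects
#' @return a \code{TripleGraph}
#' @export
TripleGraph <- function(triples = emptyTriples()) {
  if (is.null(triples$objectKind)) triples$objectKind <- "iri"
  if (is.null(triples$datatype)) triples$datatype <- NA_character_
  new("TripleGraph", triples = canonicalTriples(triples))
}

addTriple <- function(g, subject, predicate, object, objectKind = "iri",
                      datatype = NA_character_) {
  g@triples <- rbind(g@triples, data.frame(
    subject = subject, predicate = predicate, object = as.character(object),
    objectKind = objectKind, datatype = datatype, stringsAsFactors = FALSE))
  g
}

addIntTriple <- function(g, subject, predicate, value) {
  addTriple(g, subject, predicate, format(value, scientific = FALSE),
            objectKind = "literal", datatype = xsdIRI("integer"))
}

addStringTriple <- function(g, subject, predicate, value) {
  addTriple(g, subject, predicate, value, objectKind = "literal",
            datatype = xsdIRI("string"))
}

finalizeGraph <- function(g) {
  g@triples <- canonicalTriples(g@triples)
  g
}

## amortized-O(1) triple accumulator for bulk construction
newAcc <- function() {
  acc <- new.env(parent = emptyenv())
  acc$s <- list(); acc$p <- list(); acc$o <- list()
  acc$k <- list(); acc$d <- list(); acc$n <- 0L
  acc
}

accAdd <- function(acc, subject, predicate, object, objectKind = "iri",
                   datatype = NA_character_) {
  ## force all arguments before reserving the slot: an argument expression
  ## (e.g. a recursive emit call) may itself append to the accumulator
  subject <- as.character(subject)
  predicate <- as.character(predicate)
  object <- as.character(object)
  i <- acc$n + 1L
  acc$s[[i]] <- subject; acc$p[[i]] <- predicate
  acc$o[[i]] <- as.character(object)
  acc$k[[i]] <- objectKind; acc$d[[i]] <- datatype
  acc$n <- i
  invisible(acc)
}

accAddInt <- function(acc, subject, predicate, value) {
  accAdd(acc, subject, predicate, format(value, scientific = FALSE),
         "literal", xsdIRI("integer"))
}

accAddString <- function(acc, subject, predicate, value) {
  accAdd(acc, subject, predicate, value, "literal", xsdIRI("string"))
}

accGraph <- function(acc) {
  if (acc$n == 0L) return(emptyGraph())
  TripleGraph(data.frame(
    subject = unlist(acc$s), predicate = unlist(acc$p),
    object = unlist(acc$o), objectKind = unlist(acc$k),
    datatype = unlist(acc$d), stringsAsFactors = FALSE))
}

#' Number of distinct triples in a graph
#' @param g a \code{TripleGraph}
#' @export
tripleCount <- function(g) {
  nrow(canonicalTriples(g@triples))
}

#' Are two graphs the same set of statements?
#' @param a,b \code{TripleGraph}s
#' @export
graphEqual <- function(a, b) {
  isTRUE(all.equal(canonicalTriples(a@triples), canonicalTriples(b@triples),
                   check.attributes = FALSE))
}

## select objects for (subject, predicate)
graphObjects <- function(g, subject, predicate) {
  df <- g@triples
  df$object[df$subject == subject & df$predicate == predicate]
}

graphSubjects <- function(g, predicate, object) {
  df <- g@triples
  df$subject[df$predicate == predicate & df$object == object]
}

setMethod("show", "TripleGraph", function(object) {
  cat(sprintf("TripleGraph with %d statement(s)\n", tripleCount(object)))
})

## ---- Turtle writer --------------------------------------------------------

defaultPrefixes <- function() {
  c(faldo = faldoNamespace(), rdf = RDF_NS, rdfs = RDFS_NS, xsd = XSD_NS,
    owl = OWL_NS)
}

## compress an IRI into prefix:local when the local part is a safe PN_LOCAL
compressIRI <- function(iri, prefixes) {
  for (p in names(prefixes)) {
    ns <- prefixes[[p]]
    if (startsWith(iri, ns)) {
      local <- substr(iri, nchar(ns) + 1L, nchar(iri))
      if (grepl("^[A-Za-z_][A-Za-z0-9_-]*$", local))
        return(paste0(p, ":", local))
    }
  }
  paste0("<", iri, ">")
}

escapeTurtleString <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  x
}

renderNode <- function(value, kind, datatype, prefixes) {
  if (kind == "iri") {
    if (startsWith(value, "_:")) return(value)
    return(compressIRI(value, prefixes))
  }
  if (!is.na(datatype) && datatype == xsdIRI("integer")) return(value)
  lit <- paste0("\"", escapeTurtleString(value), "\"")
  if (!is.na(datatype) && datatype != xsdIRI("string"))
    lit <- paste0(lit, "^^", compressIRI(datatype, prefixes))
  lit
}

#' Serialize a graph to Turtle
#'
#' Deterministic output: prefix header, then subjects in sorted order, with
#' predicates sorted (\code{rdf:type}, written \code{a}, first) and objects
#' sorted within each predicate.
#'
#' @param g a \code{TripleGraph}
#' @param prefixes named character vector of extra prefix -> namespace
#'   mappings merged over the defaults (faldo, rdf, rdfs, xsd, owl)
#' @return character(1): the Turtle document
#' @export
toTurtle <- function(g, prefixes = character()) {
  pfx <- c(prefixes, defaultPrefixes())
  pfx <- pfx[!duplicated(names(pfx))]
  df <- canonicalTriples(g@triples)
  lines <- sprintf("@prefix %s: <%s> .", names(pfx), unname(pfx))
  lines <- c(lines, "")
  typePred <- rdfIRI("type")
  for (s in unique(df$subject)) {
    sdf <- df[df$subject == s, , drop = FALSE]
    preds <- unique(sdf$predicate)
    preds <- c(intersect(typePred, preds), setdiff(sort(preds), typePred))
    parts <- vapply(preds, function(p) {
      pdf <- sdf[sdf$predicate == p, , drop = FALSE]
      objs <- vapply(seq_len(nrow(pdf)), function(i)
        renderNode(pdf$object[i], pdf$objectKind[i], pdf$datatype[i], pfx),
        character(1))
      pname <- if (p == typePred) "a" else compressIRI(p, pfx)
      paste0(pname, " ", paste(sort(objs), collapse = ", "))
    }, character(1))
    subj <- renderNode(s, "iri", NA_character_, pfx)
    lines <- c(lines,
               paste0(subj, " ", paste(parts, collapse = " ;\n    "), " ."))
  }
  paste(lines, collapse = "\n")
}

## ---- Turtle reader --------------------------------------------------------

## tokenizer for the Turtle subset the package emits (plus blank-node
## labels and @prefix/PREFIX directives)

tokenizeTurtle <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  i <- 1L
  line <- 1L
  tokens <- list()
  push <- function(type, value) {
    tokens[[length(tokens) + 1L]] <<- list(type = type, value = value,
                                           line = line)
  }
  err <- function(msg) {
    stopFaldor("ParseError",
      sprintf("Turtle syntax error at line %d: %s", line, msg), line = line)
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch == "\n") { line <- line + 1L; i <- i + 1L; next }
    if (ch %in% c(" ", "\t", "\r")) { i <- i + 1L; next }
    if (ch == "#") {
      while (i <= n && chars[i] != "\n") i <- i + 1L
      next
    }
    if (ch == "<") {
      j <- i + 1L
      while (j <= n && chars[j] != ">") {
        if (chars[j] == "\n") err("unterminated IRI")
        j <- j + 1L
      }
      if (j > n) err("unterminated IRI")
      push("iri", paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + 1L
      next
    }
    if (ch == "\"") {
      j <- i + 1L
      out <- character()
      repeat {
        if (j > n) err("unterminated string literal")
        cj <- chars[j]
        if (cj == "\\") {
          nx <- if (j + 1L <= n) chars[j + 1L] else err("bad escape")
          out <- c(out, switch(nx, n = "\n", t = "\t", "\"" = "\"",
                               "\\" = "\\", err("bad escape")))
          j <- j + 2L
          next
        }
        if (cj == "\"") break
        if (cj == "\n") line <- line + 1L
        out <- c(out, cj)
        j <- j + 1L
      }
      i <- j + 1L
      ## optional ^^datatype
      if (i + 1L <= n && chars[i] == "^" && chars[i + 1L] == "^") {
        push("stringpart", paste(out, collapse = ""))
        push("dtmarker", "^^")
        i <- i + 2L
      } else {
        push("string", paste(out, collapse = ""))
      }
      next
    }
    if (ch %in% c(".", ";", ",")) {
      ## '.' can begin a decimal only right after digits (not emitted here)
      push("punct", ch)
      i <- i + 1L
      next
    }
    ## bare word: pname, blank node, number, 'a', @prefix
    j <- i
    while (j <= n && !chars[j] %in% c(" ", "\t", "\n", "\r", ";", ",",
                                      "\"", "<")) {
      ## a statement-final '.' is not part of the word; a '.' inside a
      ## pname local part (never emitted) is unsupported
      if (chars[j] == "." &&
          (j == n || chars[j + 1L] %in% c(" ", "\t", "\n", "\r", "")))
        break
      j <- j + 1L
    }
    word <- paste(chars[i:(j - 1L)], collapse = "")
    if (word == "") err(sprintf("unexpected character '%s'", ch))
    if (word == "a") push("a", "a")
    else if (word %in% c("@prefix", "PREFIX")) push("prefixdir", word)
    else if (grepl("^_:", word)) push("bnode", word)
    else if (grepl("^[+-]?[0-9]+$", word)) push("integer", word)
    else if (grepl("^[A-Za-z][A-Za-z0-9_.-]*:$", word))
      push("pnamens", word)  # prefix declaration name
    else if (grepl("^[A-Za-z][A-Za-z0-9_.-]*:[A-Za-z0-9_][A-Za-z0-9_.-]*$",
                   word))
      push("pname", word)
    else err(sprintf("unrecognized token '%s'", word))
    i <- j
  }
  tokens
}

#' Parse a Turtle document
#'
#' Accepts the Turtle subset the package writes: prefix directives,
#' IRIs/prefixed names, \code{a}, predicate lists with \code{;}, object
#' lists with \code{,}, integer literals and (optionally datatyped) string
#' literals, and blank-node labels.
#'
#' @param text character: the document (a vector of lines is joined)
#' @return a \code{TripleGraph}
#' @export
fromTurtle <- function(text) {
  text <- paste(text, collapse = "\n")
  toks <- tokenizeTurtle(text)
  prefixes <- defaultPrefixes()
  acc <- newAcc()
  k <- 1L
  ntok <- length(toks)
  err <- function(tok, msg) {
    stopFaldor("ParseError",
      sprintf("Turtle parse error at line %d: %s",
              if (is.null(tok)) 0L else tok$line, msg))
  }
  peek <- function() if (k <= ntok) toks[[k]] else NULL
  take <- function() {
    t <- peek()
    if (is.null(t)) err(NULL, "unexpected end of input")
    k <<- k + 1L
    t
  }
  resolve <- function(tok) {
    if (tok$type == "iri") return(tok$value)
    if (tok$type == "bnode") return(tok$value)
    if (tok$type == "pname") {
      parts <- regmatches(tok$value,
                          regexpr("^[^:]*", tok$value))
      p <- parts
      local <- substr(tok$value, nchar(p) + 2L, nchar(tok$value))
      if (!p %in% names(prefixes))
        err(tok, sprintf("undeclared prefix '%s'", p))
      return(paste0(prefixes[[p]], local))
    }
    err(tok, sprintf("expected an IRI, got %s", tok$type))
  }
  while (!is.null(peek())) {
    tok <- take()
    if (tok$type == "prefixdir") {
      nsname <- take()
      if (nsname$type != "pnamens") err(nsname, "expected prefix name")
      iri <- take()
      if (iri$type != "iri") err(iri, "expected namespace IRI")
      p <- substr(nsname$value, 1L, nchar(nsname$value) - 1L)
      prefixes[[p]] <- iri$value
      if (tok$value == "@prefix") {
        dot <- take()
        if (!(dot$type == "punct" && dot$value == "."))
          err(dot, "expected '.' after @prefix")
      }
      next
    }
    subject <- resolve(tok)
    repeat {
      ptok <- take()
      predicate <- if (ptok$type == "a") rdfIRI("type") else resolve(ptok)
      repeat {
        otok <- take()
        if (otok$type == "integer") {
          accAdd(acc, subject, predicate, otok$value, "literal",
                 xsdIRI("integer"))
        } else if (otok$type == "string") {
          accAdd(acc, subject, predicate, otok$value, "literal",
                 xsdIRI("string"))
        } else if (otok$type == "stringpart") {
          marker <- take()
          if (marker$type != "dtmarker") err(marker, "expected ^^")
          dtok <- take()
          accAdd(acc, subject, predicate, otok$value, "literal",
                 resolve(dtok))
        } else {
          accAdd(acc, subject, predicate, resolve(otok), "iri",
                 NA_character_)
        }
        sep <- take()
        if (sep$type == "punct" && sep$value == ",") next
        if (sep$type == "punct" && sep$value == ";") break
        if (sep$type == "punct" && sep$value == ".") {
          sep$value <- "END"
          break
        }
        err(sep, "expected ',', ';' or '.'")
      }
      if (sep$value == "END") break
      ## a ';' directly before '.' ends the statement too
      nxt <- peek()
      if (!is.null(nxt) && nxt$type == "punct" && nxt$value == ".") {
        take()
        break
      }
    }
  }
  accGraph(acc)
}
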