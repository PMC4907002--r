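# Canonical worked examples and small random generators shared across tests.

cheyRegion <- function() {
  parseInsdc("complement(1965072..1965461)", "NC_000913.2")
}

cheyRecord <- function() {
  FeatureRecord("cheY", cheyRegion(), featureType = "gene")
}

j02448 <- function() ReferenceSequence("J02448", 6407, "circular")

proteinIIJoin <- function() {
  parseInsdc("join(6006..6407,1..831)", "J02448")
}

proteinIIRegion <- function() {
  collapseOriginJoin(proteinIIJoin(), j02448())
}

fig2Records <- function() {
  list(
    FeatureRecord("fig2-forward",
                  gffToRegion(GffCoordinates("chr1", 1050, 2080, "+")),
                  featureType = "gene"),
    FeatureRecord("fig2-reverse",
                  gffToRegion(GffCoordinates("chr1", 1050, 2080, "-")),
                  featureType = "gene"))
}

# brute-force oracle: the set of 1-based coordinates a region covers,
# stepping from begin to end in the region's transcription direction with
# wraparound on circular references
enumerateCoveredCoords <- function(begin, end, strand, refLength = NULL,
                                   circular = FALSE) {
  step <- if (!is.na(strand) && strand == "reverse") -1L else 1L
  coords <- integer()
  x <- begin
  repeat {
    coords <- c(coords, x)
    if (x == end) break
    x <- x + step
    if (circular) {
      if (x < 1L) x <- refLength
      if (x > refLength) x <- 1L
    }
    if (length(coords) > 2L * (refLength %||% 1e6)) stop("runaway oracle")
  }
  sort(coords)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# the full set of coordinates covered by a location's normalized arcs
arcCoords <- function(loc, ref = NULL) {
  arcs <- normalizedArcs(loc, ref)
  sort(unique(unlist(mapply(seq, arcs$start, arcs$end, SIMPLIFY = FALSE))))
}

# random simple exact region for property tests; returns list with the
# region and its numeric min/max
randomExactRegion <- function(ref = "chrT", maxCoord = 10000L) {
  a <- sample.int(maxCoord, 1)
  b <- sample.int(maxCoord, 1)
  lo <- min(a, b); hi <- max(a, b)
  strand <- sample(c("forward", "reverse", NA_character_), 1)
  r <- if (!is.na(strand) && strand == "reverse")
    Region(ExactPosition(hi, ref, strand), ExactPosition(lo, ref, strand))
  else if (is.na(strand))
    Region(ExactPosition(lo, ref), ExactPosition(hi, ref))
  else
    Region(ExactPosition(lo, ref, strand), ExactPosition(hi, ref, strand))
  list(region = r, lo = lo, hi = hi, strand = strand)
}

# random INSDC location string built from the grammar, for round-trip tests
randomInsdcString <- function(maxCoord = 99999L) {
  simpleRange <- function() {
    a <- sample.int(maxCoord - 100L, 1)
    b <- a + sample.int(100L, 1)
    prefix <- sample(c("", "<"), 1, prob = c(0.85, 0.15))
    suffix <- sample(c("", ">"), 1, prob = c(0.85, 0.15))
    lhs <- if (prefix == "<") paste0("<", a) else a
    rhs <- if (suffix == ">") paste0(">", b) else b
    paste0(lhs, "..", rhs)
  }
  kind <- sample(c("range", "point", "between", "inrange", "complement",
                   "join", "order"), 1,
                 prob = c(0.3, 0.1, 0.1, 0.1, 0.2, 0.1, 0.1))
  switch(kind,
    range = simpleRange(),
    point = as.character(sample.int(maxCoord, 1)),
    between = {
      a <- sample.int(maxCoord - 1L, 1)
      paste0(a, "^", a + 1L)
    },
    inrange = {
      a <- sample.int(maxCoord - 50L, 1)
      paste0(a, ".", a + sample.int(50L, 1))
    },
    complement = paste0("complement(", simpleRange(), ")"),
    join = paste0("join(",
                  paste(replicate(sample(2:3, 1), simpleRange()),
                        collapse = ","), ")"),
    order = paste0("order(",
                   paste(replicate(sample(2:3, 1), simpleRange()),
                         collapse = ","), ")"))
}
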