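## Seeded synthetic fixture generator.
##
## One feature set is rendered into all four formats (GFF3, BED, INSDC
## feature table, Turtle) plus a manifest of the expected normalized arcs
## and a reference sidecar (id, length, topology), so converter round-trips
## and index/oracle comparisons all run against the same ground truth.
##
## The generated population mixes plain exact regions on linear references
## with origin-wrapping features on circular replicons (circularFraction)
## and fuzzy-endpoint features (fuzzyFraction).  Four canonical worked
## examples are always included deterministically: the cheY gene at
## complement(1965072..1965461), the Protein II CDS wrapped around the
## origin of the 6407 bp circular J02448 phage genome, the forward/reverse
## convention pair at 1050..2080 on chr1, and a HindIII-style cut-site
## region whose two endpoints sit on opposite strands.

fixtureReferences <- function() {
  list(
    chr1 = ReferenceSequence("chr1", 100000L, "linear"),
    chr2 = ReferenceSequence("chr2", 80000L, "linear"),
    chr3 = ReferenceSequence("chr3", 50000L, "linear"),
    plasmid1 = ReferenceSequence("plasmid1", 60000L, "circular"),
    plasmid2 = ReferenceSequence("plasmid2", 90000L, "circular"),
    NC_000913.2 = ReferenceSequence("NC_000913.2", 4641652L, "linear"),
    J02448 = ReferenceSequence("J02448", 6407L, "circular")
  )
}

workedExampleRecords <- function() {
  refs <- fixtureReferences()
  proteinII <- collapseOriginJoin(
    parseInsdc("join(6006..6407,1..831)", "J02448"), refs$J02448)
  list(
    FeatureRecord("cheY",
      parseInsdc("complement(1965072..1965461)", "NC_000913.2"),
      featureType = "gene"),
    FeatureRecord("proteinII", proteinII, featureType = "CDS"),
    FeatureRecord("fig2-forward",
      gffToRegion(GffCoordinates("chr1", 1050, 2080, "+")),
      featureType = "gene"),
    FeatureRecord("fig2-reverse",
      gffToRegion(GffCoordinates("chr1", 1050, 2080, "-")),
      featureType = "gene"),
    ## sticky-end cut site: forward-strand cut after 1001, reverse-strand
    ## cut after 1005 — endpoints on different strands
    FeatureRecord("hindiii-cut",
      Region(ExactPosition(1002, "chr1", "forward"),
             ExactPosition(1005, "chr1", "reverse")),
      featureType = "misc_feature")
  )
}

randomSyntheticRecord <- function(i, circularFraction, fuzzyFraction,
                                  refs) {
  circular <- stats::runif(1) < circularFraction
  fuzzy <- stats::runif(1) < fuzzyFraction
  strand <- sample(c("forward", "reverse", NA_character_), 1,
                   prob = c(0.45, 0.45, 0.1))
  ref <- if (circular) refs[[sample(c("plasmid1", "plasmid2"), 1)]]
         else refs[[sample(c("chr1", "chr2", "chr3"), 1)]]
  L <- ref@length
  loc <- if (circular) {
    ## origin-spanning region
    b <- sample((L - 5000L):L, 1)
    e <- sample(1:5000, 1)
    fwd <- Region(ExactPosition(b, ref@id, "forward"),
                  ExactPosition(e, ref@id, "forward"))
    if (!is.na(strand) && strand == "reverse") complementLocation(fwd)
    else if (is.na(strand)) Region(ExactPosition(b, ref@id),
                                   ExactPosition(e, ref@id))
    else fwd
  } else {
    s <- sample(100:(L - 6000L), 1)
    e <- s + sample(50:5000, 1)
    if (fuzzy) {
      slack <- sample(5:50, 1)
      beginPos <- InRangePosition(max(1L, s - slack), s, ref@id,
                                  strand = "forward")
      fwd <- Region(beginPos, ExactPosition(e, ref@id, "forward"))
      if (!is.na(strand) && strand == "reverse") complementLocation(fwd)
      else fwd
    } else {
      fwd <- Region(ExactPosition(s, ref@id, "forward"),
                    ExactPosition(e, ref@id, "forward"))
      if (!is.na(strand) && strand == "reverse") complementLocation(fwd)
      else if (is.na(strand)) Region(ExactPosition(s, ref@id),
                                     ExactPosition(e, ref@id))
      else fwd
    }
  }
  FeatureRecord(sprintf("synth%05d", i), loc,
                featureType = sample(c("gene", "exon", "CDS",
                                       "misc_feature"), 1))
}

#' Generate a deterministic synthetic fixture bundle
#'
#' @param dir output directory (created if missing)
#' @param n number of synthetic features (the worked examples are added on
#'   top unless \code{includeWorkedExamples = FALSE})
#' @param seed integer seed fixing all randomness
#' @param circularFraction fraction of synthetic features that are
#'   origin-wrapping features on a circular reference
#' @param fuzzyFraction fraction of synthetic features with a fuzzy
#'   (in-range) endpoint
#' @param includeWorkedExamples include the canonical worked examples
#' @return invisibly, a list with \code{records}, \code{refs},
#'   \code{manifest} (expected arcs) and \code{files}
#' @export
generateFixtures <- function(dir, n = 100, seed = 1,
                             circularFraction = 0.1, fuzzyFraction = 0.1,
                             includeWorkedExamples = TRUE) {
  stopifnot(n >= 0, circularFraction >= 0, circularFraction <= 1,
            fuzzyFraction >= 0, fuzzyFraction <= 1)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  refs <- fixtureReferences()

  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(oldSeed)) assign(".Random.seed", oldSeed,
                                  envir = globalenv())
  })
  set.seed(seed)

  synthetic <- lapply(seq_len(n), randomSyntheticRecord,
                      circularFraction = circularFraction,
                      fuzzyFraction = fuzzyFraction, refs = refs)
  records <- c(if (includeWorkedExamples) workedExampleRecords() else list(),
               synthetic)

  manifest <- do.call(rbind, lapply(records, function(rec) {
    do.call(rbind, lapply(rec@locations, function(loc) {
      refId <- locationReferenceId(loc)
      arcs <- normalizedArcs(loc, refs[[refId]])
      data.frame(featureId = rec@featureId, ref = refId,
                 start = arcs$start, end = arcs$end,
                 stringsAsFactors = FALSE)
    }))
  }))
  if (is.null(manifest))
    manifest <- data.frame(featureId = character(), ref = character(),
                           start = integer(), end = integer(),
                           stringsAsFactors = FALSE)
  rownames(manifest) <- NULL

  files <- c(
    gff3 = file.path(dir, "features.gff3"),
    bed = file.path(dir, "features.bed"),
    insdc = file.path(dir, "features.tbl"),
    turtle = file.path(dir, "features.ttl"),
    refs = file.path(dir, "references.tsv"),
    manifest = file.path(dir, "arcs.tsv")
  )
  writeFeatures(records, files[["gff3"]], "gff3", refs = refs)
  writeFeatures(records, files[["bed"]], "bed", refs = refs)
  writeFeatures(records, files[["insdc"]], "insdc", refs = refs,
                defaultRef = "unnamed")
  writeFeatures(records, files[["turtle"]], "turtle")
  refDf <- data.frame(
    id = vapply(refs, referenceId, character(1)),
    length = vapply(refs, referenceLength, integer(1)),
    topology = vapply(refs, topology, character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(refDf, files[["refs"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(manifest, files[["manifest"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(records = records, refs = refs, manifest = manifest,
                 files = files))
}

#' Read back a fixture reference sidecar
#'
#' @param path the references.tsv written by \code{\link{generateFixtures}}
#' @return named list of \code{ReferenceSequence}s
#' @export
readReferenceSidecar <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  refs <- lapply(seq_len(nrow(df)), function(i)
    ReferenceSequence(df$id[i], df$length[i], df$topology[i]))
  names(refs) <- df$id
  refs
}
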