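faldoType <- function(g, node) {
  g@triples$object[g@triples$subject == node &
                   g@triples$predicate == rdfIRIForTest("type")]
}

rdfIRIForTest <- function(x) {
  paste0("http://www.w3.org/1999/02/22-rdf-syntax-ns#", x)
}

test_that("emission follows the position-centred triple patterns", {
  g <- emitTriples(list(cheyRecord()))
  df <- g@triples
  posPred <- faldoIRI("position")
  lits <- df[df$predicate == posPred, ]
  expect_setequal(lits$object, c("1965461", "1965072"))

  beginNode <- lits$subject[lits$object == "1965461"]
  types <- faldoType(g, beginNode)
  expect_true(faldoIRI("ExactPosition") %in% types)
  expect_true(faldoIRI("ReverseStrandPosition") %in% types)

  refs <- df[df$predicate == faldoIRI("reference"), ]
  expect_identical(unique(refs$object),
                   "http://example.org/sequence/NC_000913.2")

  # strand typing lives on position nodes only, never on regions
  regionNodes <- df$subject[df$predicate == rdfIRIForTest("type") &
                            df$object == faldoIRI("Region")]
  strandCls <- faldoIRI(c("ForwardStrandPosition",
                          "ReverseStrandPosition", "BothStrandsPosition"))
  for (rn in regionNodes)
    expect_length(intersect(faldoType(g, rn), strandCls), 0L)
})

test_that("an empty feature list emits an empty graph", {
  expect_identical(tripleCount(emitTriples(list())), 0L)
})

test_that("identical position content pre-merges through skolem labels", {
  f1 <- FeatureRecord("a", Region(ExactPosition(42, "chr1", "forward"),
                                  ExactPosition(99, "chr1", "forward")))
  f2 <- FeatureRecord("b", Region(ExactPosition(42, "chr1", "forward"),
                                  ExactPosition(120, "chr1", "forward")))
  g <- emitTriples(list(f1, f2))
  df <- g@triples
  at42 <- unique(df$subject[df$predicate == faldoIRI("position") &
                            df$object == "42"])
  expect_length(at42, 1L)
})

test_that("parse inverts emit up to node renaming", {
  records <- c(fig2Records(), list(cheyRecord(),
    FeatureRecord("proteinII", proteinIIRegion(), featureType = "CDS"),
    FeatureRecord("joined", parseInsdc("join(1..10,21..30)", "chr2"),
                  featureType = "CDS"),
    FeatureRecord("bagged", parseInsdc("order(5..9,100..140)", "chr2")),
    FeatureRecord("fuzzy", Region(InRangePosition(90, 100, "chr3",
                                                  strand = "forward"),
                                  ExactPosition(200, "chr3", "forward"))),
    FeatureRecord("site", parseInsdc("123^124", "chr3"),
                  attributes = list(note = "cut"))))
  g <- emitTriples(records)
  back <- parseTriples(g)
  expect_length(back, length(records))
  byId <- setNames(back, vapply(back, featureId, character(1)))
  for (rec in records) {
    got <- byId[[featureId(rec)]]
    expect_false(is.null(got))
    expect_identical(featureType(got), featureType(rec))
    expect_length(featureLocations(got), length(featureLocations(rec)))
    expect_true(locationEqual(featureLocations(got)[[1]],
                              featureLocations(rec)[[1]]))
    sortAttrs <- function(a) if (length(a)) a[order(names(a))] else list()
    expect_identical(sortAttrs(featureAttributes(got)),
                     sortAttrs(featureAttributes(rec)))
  }
  # wrapped single-region record keeps begin 6006 / end 831
  p2 <- featureLocations(byId[["proteinII"]])[[1]]
  expect_identical(coordinate(beginPosition(p2)), 6006L)
  expect_identical(coordinate(endPosition(p2)), 831L)
})

test_that("a region without a begin is a dangling-position defect", {
  g <- emptyGraph()
  g <- faldor:::addTriple(g, "http://x/f", faldoIRI("location"),
                          "http://x/r")
  g <- faldor:::addTriple(g, "http://x/r", rdfIRIForTest("type"),
                          faldoIRI("Region"))
  expect_error(parseTriples(g), class = "DanglingPosition")
})

test_that("reference materialization restores exactly one reference per position", {
  records <- c(fig2Records(), list(cheyRecord(),
    FeatureRecord("fz", Region(InRangePosition(90, 100, "chr3",
                                               strand = "forward"),
                               ExactPosition(200, "chr3", "forward")))))
  full <- emitTriples(records)
  refPred <- faldoIRI("reference")
  df <- full@triples
  stripped <- TripleGraph(df[df$predicate != refPred, ])

  # record -> primary sequence links
  linkPred <- faldor:::DEFAULT_SEQUENCE_PREDICATE
  posTyped <- unique(df$subject[df$predicate == refPred])
  links <- do.call(rbind, lapply(records, function(rec) {
    refId <- faldor:::locationReferenceId(featureLocations(rec)[[1]])
    data.frame(
      subject = paste0("http://example.org/feature/", featureId(rec)),
      predicate = linkPred,
      object = paste0("http://example.org/sequence/", refId),
      objectKind = "iri", datatype = NA_character_,
      stringsAsFactors = FALSE)
  }))
  lean <- TripleGraph(rbind(stripped@triples, links))
  mat <- materializeReferences(lean)

  refCounts <- table(mat@triples$subject[mat@triples$predicate == refPred])
  expect_setequal(names(refCounts), posTyped)
  expect_true(all(refCounts == 1L))

  # equivalent to the explicitly encoded graph, and idempotent
  explicit <- TripleGraph(rbind(df, links))
  expect_true(graphEqual(mat, explicit))
  expect_true(graphEqual(materializeReferences(mat), mat))

  # a chain matching nothing leaves the graph unchanged
  noop <- materializeReferences(lean,
    chain = list(chainHop("http://nowhere/p")))
  expect_true(graphEqual(noop, lean))
})

test_that("hasKey merge collapses equal positions across equated references", {
  mk <- function(id, ref) FeatureRecord(id,
    Region(ExactPosition(42, ref, "forward"),
           ExactPosition(99, ref, "forward")))
  g <- emitTriples(list(mk("recA", "seqX"), mk("recB", "seqY")))
  sameAs <- data.frame(
    subject = "http://example.org/sequence/seqX",
    predicate = "http://www.w3.org/2002/07/owl#sameAs",
    object = "http://example.org/sequence/seqY",
    objectKind = "iri", datatype = NA_character_,
    stringsAsFactors = FALSE)
  g2 <- TripleGraph(rbind(g@triples, sameAs))

  merged <- mergeByKey(g2)
  posPred <- faldoIRI("position")
  at42 <- unique(merged@triples$subject[
    merged@triples$predicate == posPred & merged@triples$object == "42"])
  expect_length(at42, 1L)
  expect_lte(tripleCount(merged), tripleCount(g2))

  # idempotent
  expect_true(graphEqual(mergeByKey(merged), merged))
  # confluent under statement shuffling
  set.seed(409)
  shuf <- TripleGraph(g2@triples[sample(nrow(g2@triples)), ])
  expect_true(graphEqual(mergeByKey(shuf), merged))
})

test_that("merge leaves duplicate-free graphs unchanged and matches a group-by oracle", {
  g <- emitTriples(fig2Records())
  expect_true(graphEqual(mergeByKey(g), g))

  # three distinct node labels for one (position, reference, strand) key
  base <- emitTriples(list(cheyRecord()))
  df <- base@triples
  clone <- function(df, suffix) {
    hit <- grepl("^http://example.org/(position|region)/", df$subject)
    df$subject[hit] <- paste0(df$subject[hit], suffix)
    hitO <- df$objectKind == "iri" &
      grepl("^http://example.org/(position|region)/", df$object)
    df$object[hitO] <- paste0(df$object[hitO], suffix)
    df
  }
  tripled <- TripleGraph(rbind(df, clone(df, "-v2"), clone(df, "-v3")))
  merged <- mergeByKey(tripled)

  posPred <- faldoIRI("position")
  mdf <- merged@triples
  # brute-force oracle: group position nodes by (literal, reference)
  lits <- mdf[mdf$predicate == posPred, ]
  refs <- mdf[mdf$predicate == faldoIRI("reference"), ]
  refOf <- setNames(refs$object, refs$subject)
  key <- paste(lits$object, refOf[lits$subject])
  expect_identical(length(unique(lits$subject)), length(unique(key)))
})

test_that("contradictory strand typing on one node is rejected at parse", {
  g <- emitTriples(list(cheyRecord()))
  df <- g@triples
  node <- df$subject[df$predicate == faldoIRI("position")][1]
  extra <- data.frame(subject = node,
                      predicate = rdfIRIForTest("type"),
                      object = faldoIRI("ForwardStrandPosition"),
                      objectKind = "iri", datatype = NA_character_,
                      stringsAsFactors = FALSE)
  g2 <- TripleGraph(rbind(df, extra))
  expect_error(parseTriples(g2), class = "ContradictoryStrand")
  v <- validateFeatures(g2, profile = "core")
  expect_true("strand-contradiction" %in% v$ruleId)
})
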