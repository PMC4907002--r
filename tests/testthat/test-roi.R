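fig2Index <- function() {
  refs <- list(chr1 = ReferenceSequence("chr1", 100000, "linear"))
  buildRoiIndex(fig2Records(), refs)
}

test_that("the index holds one arc per simple feature", {
  idx <- fig2Index()
  expect_identical(nrow(idx@arcs), 2L)
  expect_setequal(idx@arcs$ref, "chr1")

  empty <- buildRoiIndex(list())
  expect_identical(nrow(empty@arcs), 0L)
  expect_identical(roiQuery(empty, "chr1", 1, 10), character())
})

test_that("origin-wrapping features contribute one arc per segment", {
  refs <- list(J02448 = j02448())
  idx <- buildRoiIndex(
    list(FeatureRecord("proteinII", proteinIIRegion(), featureType = "CDS")),
    refs)
  expect_identical(nrow(idx@arcs), 2L)
  expect_identical(unique(idx@arcs$id), "proteinII")
  # found via its high arc
  expect_identical(roiQuery(idx, "J02448", 6300, 6350), "proteinII")
  # and via its low arc
  expect_identical(roiQuery(idx, "J02448", 100, 200), "proteinII")
  # but not in the gap
  expect_identical(roiQuery(idx, "J02448", 1000, 5000), character())
})

test_that("queries return exactly the overlapping features, sorted", {
  idx <- fig2Index()
  expect_identical(roiQuery(idx, "chr1", 2000, 2100),
                   c("fig2-forward", "fig2-reverse"))
  expect_identical(roiQuery(idx, "chr1", 1, 1049), character())
  expect_identical(roiQuery(idx, "chr1", 2080, 2080),
                   c("fig2-forward", "fig2-reverse"))
  expect_identical(roiQuery(idx, "chrUnknown", 1, 10), character())
  expect_identical(roiQuery(idx, "chr1", 2000, 2100, strand = "reverse"),
                   "fig2-reverse")
})

test_that("wrapped queries split at the origin and union results", {
  refs <- list(J02448 = j02448())
  recs <- list(
    FeatureRecord("nearEnd", Region(ExactPosition(6300, "J02448", "forward"),
                                    ExactPosition(6350, "J02448", "forward"))),
    FeatureRecord("nearStart", Region(ExactPosition(5, "J02448", "forward"),
                                      ExactPosition(50, "J02448", "forward"))),
    FeatureRecord("middle", Region(ExactPosition(3000, "J02448", "forward"),
                                   ExactPosition(3100, "J02448", "forward"))))
  idx <- buildRoiIndex(recs, refs)
  hit <- roiQuery(idx, "J02448", 6200, 100)
  expect_setequal(hit, c("nearEnd", "nearStart"))
  expect_identical(hit, roiQueryNaive(idx, "J02448", 6200, 100))
})

test_that("NCL results equal the naive scan on random data (property)", {
  set.seed(410)
  refs <- list(
    lin1 = ReferenceSequence("lin1", 100000, "linear"),
    lin2 = ReferenceSequence("lin2", 60000, "linear"),
    circ = ReferenceSequence("circ", 50000, "circular"))
  feats <- lapply(seq_len(300), function(i) {
    pick <- stats::runif(1)
    if (pick < 0.1) {
      b <- sample(45000:50000, 1); e <- sample.int(5000, 1)
      FeatureRecord(sprintf("w%03d", i),
        Region(ExactPosition(b, "circ", "forward"),
               ExactPosition(e, "circ", "forward")))
    } else if (pick < 0.2) {
      s <- sample.int(90000, 1)
      FeatureRecord(sprintf("f%03d", i),
        Region(InRangePosition(max(1, s - 30), s, "lin1",
                               strand = "forward"),
               ExactPosition(s + sample.int(3000, 1), "lin1", "forward")))
    } else {
      refId <- sample(c("lin1", "lin2"), 1)
      x <- randomExactRegion(refId, 50000L)
      FeatureRecord(sprintf("e%03d", i), x$region)
    }
  })
  idx <- buildRoiIndex(feats, refs)
  for (q in seq_len(300)) {
    refId <- sample(names(refs), 1)
    a <- sample.int(55000, 1)
    b <- min(a + sample.int(8000, 1), 100000L)
    expect_identical(roiQuery(idx, refId, a, b),
                     roiQueryNaive(idx, refId, a, b))
  }
  # wrapped random queries on the circular reference
  for (q in seq_len(50)) {
    a <- sample(40000:50000, 1); b <- sample.int(8000, 1)
    expect_identical(roiQuery(idx, "circ", a, b),
                     roiQueryNaive(idx, "circ", a, b))
  }
})

test_that("results are invariant under feature input permutation", {
  set.seed(411)
  refs <- list(lin1 = ReferenceSequence("lin1", 100000, "linear"))
  feats <- lapply(seq_len(120), function(i) {
    x <- randomExactRegion("lin1", 90000L)
    FeatureRecord(sprintf("e%03d", i), x$region)
  })
  idx1 <- buildRoiIndex(feats, refs)
  idx2 <- buildRoiIndex(sample(feats), refs)
  for (q in seq_len(40)) {
    a <- sample.int(90000, 1); b <- min(a + sample.int(5000, 1), 100000L)
    expect_identical(roiQuery(idx1, "lin1", a, b),
                     roiQuery(idx2, "lin1", a, b))
  }
})

test_that("a whole-reference query returns every feature exactly once", {
  refs <- list(J02448 = j02448(),
               chr1 = ReferenceSequence("chr1", 100000, "linear"))
  recs <- c(fig2Records(),
            list(FeatureRecord("proteinII", proteinIIRegion(),
                               featureType = "CDS")))
  idx <- buildRoiIndex(recs, refs)
  all1 <- roiQuery(idx, "chr1", 1, 100000)
  expect_identical(all1, c("fig2-forward", "fig2-reverse"))
  allc <- roiQuery(idx, "J02448", 1, 6407)
  expect_identical(allc, "proteinII")   # wrapped feature not duplicated
})
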