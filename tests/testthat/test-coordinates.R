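test_that("GFF conversion assigns the biological start by strand", {
  fwd <- gffToRegion(GffCoordinates("chr1", 1050, 2080, "+"))
  expect_identical(coordinate(beginPosition(fwd)), 1050L)
  expect_identical(strand(beginPosition(fwd)), "forward")

  rev <- gffToRegion(GffCoordinates("chr1", 1050, 2080, "-"))
  expect_identical(coordinate(beginPosition(rev)), 2080L)
  expect_identical(coordinate(endPosition(rev)), 1050L)
  expect_identical(strand(beginPosition(rev)), "reverse")

  dot <- gffToRegion(GffCoordinates("chr1", 9, 9, "."))
  expect_identical(coordinate(beginPosition(dot)), 9L)
  expect_true(is.na(strand(beginPosition(dot))))

  expect_error(GffCoordinates("chr1", 20, 10), class = "InvalidInterval")
})

test_that("regions export to the strand-independent start<=end scheme", {
  g <- regionToGff(cheyRegion())
  expect_identical(g$start, 1965072L)
  expect_identical(g$end, 1965461L)
  expect_identical(g$strand, "-")

  # mutual inverses on the valid domain
  orig <- GffCoordinates("chr1", 1050, 2080, "+")
  expect_identical(regionToGff(gffToRegion(orig)), orig)

  # opposite-strand endpoints (cut sites) have no start<=end rendering
  h <- Region(ExactPosition(1002, "chr1", "forward"),
              ExactPosition(1005, "chr1", "reverse"))
  expect_error(regionToGff(h), class = "NotExpressible")
  # nor do origin-wrapping regions
  expect_error(regionToGff(proteinIIRegion()), class = "NotExpressible")
})

test_that("BED half-open zero-based coordinates convert exactly", {
  r <- bedToRegion(BedCoordinates("chr1", 1049, 2080, "+"))
  expect_identical(coordinate(beginPosition(r)), 1050L)
  expect_identical(coordinate(endPosition(r)), 2080L)

  first <- bedToRegion(BedCoordinates("chr1", 0, 1, "+"))
  expect_identical(coordinate(beginPosition(first)), 1L)
  expect_identical(coordinate(endPosition(first)), 1L)

  expect_error(BedCoordinates("chr1", 5, 5), class = "InvalidInterval")

  b <- regionToBed(gffToRegion(GffCoordinates("chr1", 1050, 2080, "+")))
  expect_identical(b$chromStart, 1049L)
  expect_identical(b$chromEnd, 2080L)
  expect_identical(b$strand, "+")

  one <- regionToBed(Region(ExactPosition(1, "x"), ExactPosition(1, "x")))
  expect_identical(c(one$chromStart, one$chromEnd), c(0L, 1L))
  expect_error(regionToBed(proteinIIRegion()), class = "NotExpressible")
})

test_that("every rendering covers the identical base set (property)", {
  set.seed(408)
  for (i in 1:50) {
    start <- sample.int(9000, 1)
    end <- start + sample.int(999, 1) - 1L
    strandSym <- sample(c("+", "-"), 1)
    covered <- start:end

    g <- GffCoordinates("chrT", start, end, strandSym)
    rg <- gffToRegion(g)
    expect_identical(arcCoords(rg), covered)

    b <- regionToBed(rg)
    expect_identical(arcCoords(bedToRegion(b)), covered)
    expect_identical((b$chromStart + 1L):b$chromEnd, covered)

    ins <- serializeInsdc(rg, "chrT")
    expect_identical(arcCoords(parseInsdc(ins, "chrT")), covered)

    # GFF length identity under the numerically convenient scheme
    g2 <- regionToGff(rg)
    expect_identical(regionLength(rg), g2$end - g2$start + 1L)

    # full inverse loops
    expect_identical(regionToGff(gffToRegion(g)), g)
    expect_true(locationEqual(bedToRegion(regionToBed(rg)), rg))
  }
})

test_that("unknown-strand GFF maps to untyped positions, not a strand value", {
  q <- GffCoordinates("chr1", 5, 10, "?")
  r <- gffToRegion(q)
  expect_true(is.na(strand(beginPosition(r))))
  expect_true(is.na(strand(endPosition(r))))
})
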