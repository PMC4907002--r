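test_that("the biological start is the begin position, strand regardless", {
  fwd <- Region(ExactPosition(1050, "chr1", "forward"),
                ExactPosition(2080, "chr1", "forward"))
  rev <- Region(ExactPosition(2080, "chr1", "reverse"),
                ExactPosition(1050, "chr1", "reverse"))
  one <- Region(ExactPosition(7, "x", "forward"),
                ExactPosition(7, "x", "forward"))
  expect_identical(coordinate(biologicalStart(fwd)), 1050L)
  expect_identical(coordinate(biologicalStart(rev)), 2080L)
  expect_identical(coordinate(biologicalStart(one)), 7L)
  expect_identical(coordinate(biologicalEnd(rev)), 1050L)
})

test_that("normalized arcs: linear, single-base, and circular wrap", {
  chey <- cheyRegion()
  a <- normalizedArcs(chey)
  expect_equal(a$start, 1965072L)
  expect_equal(a$end, 1965461L)

  p5 <- Region(ExactPosition(5, "x"), ExactPosition(5, "x"))
  expect_equal(normalizedArcs(p5), data.frame(start = 5L, end = 5L))

  arcs <- normalizedArcs(proteinIIRegion(), j02448())
  expect_equal(arcs, data.frame(start = c(6006L, 1L),
                                end = c(6407L, 831L)))
})

test_that("arc errors carry their condition classes", {
  multi <- Region(ExactPosition(10, "contigA"), ExactPosition(99, "contigB"))
  expect_error(normalizedArcs(multi), class = "MultiReferenceRegion")

  wrap <- Region(ExactPosition(6006, "plasmidX", "forward"),
                 ExactPosition(831, "plasmidX", "forward"))
  noLen <- ReferenceSequence("plasmidX", NA, "circular")
  expect_error(normalizedArcs(wrap, noLen), class = "MissingLength")
})

test_that("region length uses inclusive one-based counting", {
  expect_identical(regionLength(cheyRegion()), 390L)
  expect_identical(regionLength(proteinIIRegion(), j02448()), 1233L)
  expect_identical(
    regionLength(Region(ExactPosition(9, "x"), ExactPosition(9, "x"))), 1L)
})

test_that("circular region length matches brute-force coordinate stepping", {
  set.seed(401)
  for (i in 1:25) {
    L <- sample(100:10000, 1)
    ref <- ReferenceSequence("circ", L, "circular")
    b <- sample.int(L, 1); e <- sample.int(L, 1)
    strand <- sample(c("forward", "reverse"), 1)
    r <- if (strand == "forward")
      Region(ExactPosition(b, "circ", "forward"),
             ExactPosition(e, "circ", "forward"))
    else
      Region(ExactPosition(b, "circ", "reverse"),
             ExactPosition(e, "circ", "reverse"))
    oracle <- enumerateCoveredCoords(b, e, strand, L, circular = TRUE)
    expect_identical(regionLength(r, ref), length(oracle))
    expect_identical(arcCoords(r, ref), oracle)
  }
})

test_that("fuzzy envelopes bound every admissible coordinate", {
  expect_equal(fuzzyEnvelope(ExactPosition(100, "x")), c(100L, 100L))
  expect_equal(fuzzyEnvelope(OneOfPosition(list(1888, 1901), "x")),
               c(1888L, 1901L))
  expect_equal(fuzzyEnvelope(InRangePosition(1, 17, "x")), c(1L, 17L))
  expect_equal(fuzzyEnvelope(InBetweenPosition(123, 124, "x")),
               c(123L, 124L))

  # by enumeration: every candidate of a one-of lies inside the envelope
  set.seed(402)
  for (i in 1:20) {
    opts <- sample.int(5000, sample(2:6, 1))
    env <- fuzzyEnvelope(OneOfPosition(as.list(opts), "x"))
    expect_true(all(opts >= env[1] & opts <= env[2]))
    expect_true(env[1] %in% opts && env[2] %in% opts)
  }
})

test_that("unbounded fuzzy sides use the reference length or signal", {
  p <- InRangePosition(lowBound = 900, reference = "chrZ")
  expect_error(fuzzyEnvelope(p), class = "UnboundedEnvelope")
  ref <- ReferenceSequence("chrZ", 1000, "linear")
  expect_equal(fuzzyEnvelope(p, ref), c(900L, 1000L))
  q <- InRangePosition(highBound = 17, reference = "chrZ")
  expect_equal(fuzzyEnvelope(q), c(1L, 17L))
})

test_that("length equals span for linear same-strand regions (property)", {
  set.seed(403)
  for (i in 1:50) {
    x <- randomExactRegion()
    a <- normalizedArcs(x$region)
    expect_identical(regionLength(x$region), a$end - a$start + 1L)
    expect_identical(c(a$start, a$end), c(x$lo, x$hi))
  }
})

test_that("strand flip plus endpoint swap preserves the normalized interval", {
  set.seed(404)
  for (i in 1:50) {
    x <- randomExactRegion()
    r <- x$region
    flipped <- complementLocation(r)
    expect_identical(normalizedArcs(r), normalizedArcs(flipped))
    expect_true(locationEqual(complementLocation(flipped), r) ||
                is.na(x$strand))
  }
})
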