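test_that("positions validate their invariants", {
  p <- ExactPosition(1965461, "NC_000913.2", "reverse")
  expect_s4_class(p, "ExactPosition")
  expect_identical(coordinate(p), 1965461L)
  expect_identical(reference(p), "NC_000913.2")
  expect_identical(strand(p), "reverse")

  expect_error(ExactPosition(0, "x"), class = "InvalidCoordinate")
  expect_error(ExactPosition(-3, "x"), class = "InvalidCoordinate")
  expect_error(ExactPosition(5, "x", strand = "up"),
               class = "InvalidStrand")
  expect_error(validObject(new("ExactPosition", coordinate = 5L,
                               reference = "", strand = NA_character_)))
})

test_that("absence of a strand claim is legal and distinct from any claim", {
  p <- ExactPosition(10, "chr1")
  expect_true(is.na(strand(p)))
  q <- ExactPosition(10, "chr1", "forward")
  expect_false(identical(positionKey(p), positionKey(q)))
})

test_that("terminal positions pin their coordinates", {
  n <- TerminalPosition("N", reference = "P12345")
  expect_identical(coordinate(n), 1L)
  expect_error(TerminalPosition("N", coordinate = 5, reference = "P12345"))
  c2 <- TerminalPosition("C", coordinate = 208, reference = "P12345")
  expect_identical(coordinate(c2), 208L)
})

test_that("fuzzy position constructors enforce their structure", {
  expect_error(InRangePosition(reference = "x"))
  r <- InRangePosition(1, 17, reference = "x")
  expect_s4_class(r, "InRangePosition")
  expect_error(InRangePosition(20, 10, reference = "x"))

  expect_error(OneOfPosition(list(5, 5), "x"))
  o <- OneOfPosition(list(1888, 1901), "x")
  expect_length(positionOptions(o), 2L)

  b <- InBetweenPosition(123, 124, "x")
  expect_identical(coordinate(afterPosition(b)), 123L)
  expect_error(InBetweenPosition(123, 125, "x"))
  # circular adjacency across the origin (length -> 1) is allowed
  expect_s4_class(InBetweenPosition(6407, 1, "J02448"), "InBetweenPosition")
})

test_that("regions allow biological orientation and split references", {
  r <- Region(ExactPosition(2080, "chr1", "reverse"),
              ExactPosition(1050, "chr1", "reverse"))
  expect_identical(coordinate(beginPosition(r)), 2080L)
  # trans-spliced / multi-contig: endpoints on different references are legal
  m <- Region(ExactPosition(10, "contigA"), ExactPosition(99, "contigB"))
  expect_s4_class(m, "Region")
  # and on different strands (sticky-end cut sites)
  h <- Region(ExactPosition(1002, "chr1", "forward"),
              ExactPosition(1005, "chr1", "reverse"))
  expect_s4_class(h, "Region")
})

test_that("collections distinguish ordered and unordered comparison", {
  r1 <- Region(ExactPosition(1, "x", "forward"),
               ExactPosition(5, "x", "forward"))
  r2 <- Region(ExactPosition(10, "x", "forward"),
               ExactPosition(20, "x", "forward"))
  lst <- RegionCollection(list(r1, r2), kind = "list")
  bag <- RegionCollection(list(r1, r2), kind = "bag")
  expect_false(locationEqual(lst, RegionCollection(list(r2, r1), "list")))
  expect_true(locationEqual(bag, RegionCollection(list(r2, r1), "bag")))
  expect_false(locationEqual(lst, bag))
})

test_that("feature records require at least one location", {
  expect_error(FeatureRecord("f1", list()))
  f <- FeatureRecord("f1", ExactPosition(42, "chr1"),
                     attributes = list(note = "single base"))
  expect_length(featureLocations(f), 1L)
  expect_identical(featureAttributes(f)$note, "single base")
})

test_that("reference sequences validate topology and length", {
  expect_error(ReferenceSequence("r", topology = "weird"))
  circ <- ReferenceSequence("J02448", 6407, "circular")
  expect_true(isCircular(circ))
  expect_identical(referenceLength(circ), 6407L)
})

test_that("position equality is structural over class, coordinates, strand and reference", {
  a <- ExactPosition(42, "chr1", "forward")
  b <- ExactPosition(42, "chr1", "forward")
  expect_true(locationEqual(a, b))
  expect_false(locationEqual(a, ExactPosition(42, "chr2", "forward")))
  expect_false(locationEqual(a, ExactPosition(43, "chr1", "forward")))
  expect_false(locationEqual(a, ExactPosition(42, "chr1", "reverse")))
  # class matters: an exact 42 is not a width-zero in-range at 42
  expect_false(locationEqual(a, InRangePosition(42, 42, "chr1",
                                                strand = "forward")))
})
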