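test_that("parsing the canonical location forms", {
  chey <- parseInsdc("complement(1965072..1965461)", "NC_000913.2")
  expect_s4_class(chey, "Region")
  expect_identical(coordinate(beginPosition(chey)), 1965461L)
  expect_identical(coordinate(endPosition(chey)), 1965072L)
  expect_identical(strand(beginPosition(chey)), "reverse")

  plain <- parseInsdc("1050..2080", "chr1")
  expect_identical(coordinate(beginPosition(plain)), 1050L)
  expect_identical(coordinate(endPosition(plain)), 2080L)
  expect_identical(strand(beginPosition(plain)), "forward")

  jn <- parseInsdc("join(6006..6407,1..831)", "J02448")
  expect_s4_class(jn, "RegionCollection")
  expect_identical(collectionKind(jn), "list")
  expect_identical(coordinate(beginPosition(collectionMembers(jn)[[1]])),
                   6006L)
  expect_identical(coordinate(endPosition(collectionMembers(jn)[[2]])),
                   831L)

  od <- parseInsdc("order(10..20,30..40)", "x")
  expect_identical(collectionKind(od), "bag")

  bw <- parseInsdc("123^124", "x")
  expect_s4_class(bw, "InBetweenPosition")
  expect_identical(coordinate(afterPosition(bw)), 123L)
  expect_identical(coordinate(beforePosition(bw)), 124L)
})

test_that("fuzzy operators map to in-range positions", {
  r <- parseInsdc("<17..206", "x")
  b <- beginPosition(r)
  expect_s4_class(b, "InRangePosition")
  expect_null(lowBound(b))
  expect_identical(coordinate(highBound(b)), 17L)

  r2 <- parseInsdc("4821..>5000", "x")
  e2 <- endPosition(r2)
  expect_null(highBound(e2))
  expect_identical(coordinate(lowBound(e2)), 5000L)

  p <- parseInsdc("102.110", "x")
  expect_s4_class(p, "InRangePosition")
  expect_identical(coordinate(lowBound(p)), 102L)

  r3 <- parseInsdc("(5.10)..(15.20)", "x")
  expect_s4_class(beginPosition(r3), "InRangePosition")
  expect_s4_class(endPosition(r3), "InRangePosition")
})

test_that("remote accessions set the per-position reference", {
  r <- parseInsdc("J00194.1:100..202", "host")
  expect_identical(reference(beginPosition(r)), "J00194.1")
  jn <- parseInsdc("join(100..200,J00194.1:1..50)", "host")
  m <- collectionMembers(jn)
  expect_identical(reference(beginPosition(m[[1]])), "host")
  expect_identical(reference(beginPosition(m[[2]])), "J00194.1")
})

test_that("parse errors carry class and offset", {
  expect_error(parseInsdc("10..", "x"), class = "ParseError")
  expect_error(parseInsdc("join(10..20", "x"), class = "ParseError")
  expect_error(parseInsdc("10..20extra", "x"), class = "ParseError")
  expect_error(parseInsdc("0..5", "x"), class = "InvalidCoordinate")
  expect_error(parseInsdc("join()", "x"), class = "EmptyCompound")
  err <- tryCatch(parseInsdc("10..x", "x"), faldorError = identity)
  expect_true(err$offset > 1L)
})

test_that("serialization is the inverse of parsing", {
  chey <- cheyRegion()
  expect_identical(serializeInsdc(chey, "NC_000913.2"),
                   "complement(1965072..1965461)")
  s <- "join(6006..6407,1..831)"
  expect_identical(serializeInsdc(parseInsdc(s, "J02448"), "J02448"), s)

  fr <- parseInsdc("<17..206", "x")
  expect_identical(serializeInsdc(fr, "x"), "<17..206")

  expect_error(
    serializeInsdc(Region(ExactPosition(1, "a"), ExactPosition(9, "b")),
                   "a"),
    class = "NotExpressible")
  expect_error(
    serializeInsdc(ExactPosition(5, "x", "both"), "x"),
    class = "NotExpressible")
})

test_that("canonical strings round-trip through parse and serialize (property)", {
  set.seed(405)
  for (i in 1:200) {
    s <- randomInsdcString()
    loc <- parseInsdc(s, "acc")
    expect_identical(serializeInsdc(loc, "acc"), s)
    # model-level round trip too
    expect_true(locationEqual(parseInsdc(serializeInsdc(loc, "acc"), "acc"),
                              loc))
  }
})

test_that("complement preserves length for random exact ranges", {
  set.seed(406)
  for (i in 1:40) {
    a <- sample.int(9000, 1)
    b <- a + sample.int(999, 1)
    fwd <- parseInsdc(sprintf("%d..%d", a, b), "x")
    rev <- parseInsdc(sprintf("complement(%d..%d)", a, b), "x")
    expect_identical(regionLength(fwd), b - a + 1L)
    expect_identical(regionLength(rev), b - a + 1L)
    expect_identical(arcCoords(fwd), arcCoords(rev))
  }
})

test_that("complement(join(...)) reverses member order and strands", {
  loc <- parseInsdc("complement(join(100..200,300..400))", "x")
  expect_s4_class(loc, "RegionCollection")
  m <- collectionMembers(loc)
  expect_identical(coordinate(beginPosition(m[[1]])), 400L)
  expect_identical(strand(beginPosition(m[[1]])), "reverse")
  expect_identical(coordinate(endPosition(m[[2]])), 100L)
  expect_identical(serializeInsdc(loc, "x"),
                   "complement(join(100..200,300..400))")
})

test_that("origin-spanning joins collapse on circular references only", {
  collapsed <- collapseOriginJoin(proteinIIJoin(), j02448())
  expect_s4_class(collapsed, "Region")
  expect_identical(coordinate(beginPosition(collapsed)), 6006L)
  expect_identical(coordinate(endPosition(collapsed)), 831L)

  # covered coordinates identical before and after the collapse
  expect_identical(arcCoords(proteinIIJoin(), j02448()),
                   arcCoords(collapsed, j02448()))
  expect_identical(regionLength(collapsed, j02448()),
                   regionLength(proteinIIJoin(), j02448()))

  # not origin-adjacent: unchanged
  keep <- parseInsdc("join(10..20,30..40)", "c")
  expect_true(locationEqual(
    collapseOriginJoin(keep, ReferenceSequence("c", 50, "circular")), keep))
  # linear topology gate: unchanged
  lin <- parseInsdc("join(40..50,1..5)", "l")
  expect_true(locationEqual(
    collapseOriginJoin(lin, ReferenceSequence("l", 50, "linear")), lin))
  # order(...) semantics are too weak to collapse
  od <- parseInsdc("order(6006..6407,1..831)", "J02448")
  expect_true(locationEqual(collapseOriginJoin(od, j02448()), od))
})

test_that("reverse-strand origin joins collapse symmetrically", {
  loc <- parseInsdc("complement(join(6006..6407,1..831))", "J02448")
  collapsed <- collapseOriginJoin(loc, j02448())
  expect_s4_class(collapsed, "Region")
  expect_identical(strand(beginPosition(collapsed)), "reverse")
  expect_identical(arcCoords(collapsed, j02448()),
                   arcCoords(loc, j02448()))
})

test_that("collapse random origin joins preserves the covered set (property)", {
  set.seed(407)
  for (i in 1:25) {
    L <- sample(1000:10000, 1)
    ref <- ReferenceSequence("c", L, "circular")
    b <- sample(2:L, 1)
    e <- sample.int(b - 1L, 1)
    s <- sprintf("join(%d..%d,1..%d)", b, L, e)
    col <- parseInsdc(s, "c")
    collapsed <- collapseOriginJoin(col, ref)
    expect_s4_class(collapsed, "Region")
    expect_identical(arcCoords(collapsed, ref), arcCoords(col, ref))
    # and the expansion is its inverse
    back <- expandOriginJoin(collapsed, ref)
    expect_true(locationEqual(back, col))
  }
})

test_that("exploding compound locations preserves members and order flag", {
  jn <- parseInsdc("join(1..10,21..30,41..50)", "x")
  ex <- explodeExons(jn)
  expect_length(ex, 3L)
  expect_true(attr(ex, "ordered"))
  expect_identical(coordinate(beginPosition(ex[[2]])), 21L)

  od <- parseInsdc("order(10..20,30..40)", "x")
  ex2 <- explodeExons(od)
  expect_length(ex2, 2L)
  expect_false(attr(ex2, "ordered"))

  single <- parseInsdc("join(5..9)", "x")
  expect_length(explodeExons(single), 1L)
})
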