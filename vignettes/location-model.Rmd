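---
title: "A strand-aware model of sequence feature locations"
author: "faldor authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A strand-aware model of sequence feature locations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faldor)
```

## The problem

Every major annotation format encodes "where is this feature on the
sequence" differently.  GFF3/GTF use 1-based inclusive intervals with
`start <= end` regardless of strand; BED uses 0-based half-open intervals;
INSDC feature tables use 1-based inclusive location strings in which the
written order reflects *biology* (`complement(1965072..1965461)` is a gene
whose transcription starts at 1,965,461).  The mixture of conventions is a
standing source of off-by-one errors, and none of the line formats can
express what databases routinely need: a position that is only partially
known, a feature whose start and end sit on different contigs or strands,
or a feature crossing the origin of a circular replicon.

`faldor` implements the FALDO model of feature locations as S4 classes and
provides converters between the formats' location dialects, RDF/Turtle
emission and parsing, the model's two reasoning rules, validation profiles
and interval queries.  The package stores *where* features are, never the
sequence residues themselves, and performs no lift-over arithmetic between
assemblies.

## The model and its assumptions

Three decisions, taken together, make the model closed under the awkward
cases:

1. **Coordinates are 1-based, inclusive, and always counted from the
   5' end of the forward strand**, even for reverse-strand features.  A
   region with `begin == end` has length 1, and positions on opposite
   strands of a linear molecule are comparable without knowing the
   sequence length.
2. **Strand and reference sequence are properties of the position, not the
   region.**  A region's two endpoints may therefore sit on different
   contigs (a gene spanning a draft-assembly gap, trans-spliced genes) or
   on different strands (the HindIII sticky-end cut site, whose forward
   and reverse cuts fall four bases apart).  A single base needs no
   artificial length-one region: a bare position is a legal location.
3. **A region's `begin` is the biological start.**  For reverse-strand
   features `begin` is numerically *larger* than `end`.  This is the
   INSDC/Chado reading, not the GFF one; the GFF rendering is recovered by
   `regionToGff()`, which is strand-independent `min`/`max` bookkeeping.

"Strand unknown" is deliberately *not* a value.  A position either carries
a strand claim (`forward`, `reverse`, `both`) or carries none (`NA`).  A
sentinel "unknown strand" class would let two merged datasets type one
position both forward-stranded and unknown-stranded — a contradiction that
absence cannot produce.  The GFF symbols `.` and `?` both map to untyped
positions; `?` is additionally recorded as an attribute so the distinction
survives a round trip.

Partial knowledge uses three fuzzy position classes: in-range (the
position lies inside an interval, possibly unbounded on one side — INSDC
`<n`, `>n`, `n.m`), one-of (an explicit candidate set), and in-between (a
point between two adjacent bases, INSDC `n^m` — cut sites, insertion
points).  `fuzzyEnvelope()` reduces any position to the smallest interval
guaranteed to contain it; an unbounded low side defaults to 1 and an
unbounded high side to the reference length *only inside the envelope
computation* — the stored model keeps absent bounds absent, so fidelity is
never silently lost.

## Circular references and the wrap rule

On a circular replicon a feature may cross the origin.  INSDC splits such
features into `join(a..L, 1..b)`; the model prefers the single region
`begin = a, end = b`.  `collapseOriginJoin()` performs that rewrite (and
`expandOriginJoin()` its inverse) when the reference is circular with
known length and the two ordered members are origin-adjacent;
`order(...)` collections never collapse because their member order carries
no meaning.

A collapsed region is recognized as wrapping by a strand-aware rule: on a
circular reference a region wraps when its numeric endpoint order
contradicts its strand's normal orientation — `begin > end` for forward or
untyped regions, `begin < end` for reverse-strand regions (whose begin is
normally the larger coordinate).  On a linear reference nothing wraps, and
a reverse-strand `begin > end` is ordinary.  `normalizedArcs()` turns any
region into one or two `start <= end` arcs; arcs are the common currency
for interval queries, for GFF/BED export and for the covered-base-set
invariants the tests enforce by brute-force enumeration.

One subtlety is worth recording: for an origin-spanning CDS written
without `complement()`, the parsed members are forward-typed, so the
collapsed region is forward-typed with `begin = 6006 > end = 831` on a
6,407 bp genome, and its arcs are `[6006, 6407]` and `[1, 831]` — the
covered set is identical before and after collapsing, which the tests
check by enumeration.

## RDF emission and the two reasoning rules

`emitTriples()` renders records in the ontology's shapes: feature
→ `location` → region, region → `begin`/`end` → positions; each position
node is typed with its position class plus a strand class when a claim
exists, and carries its integer offset and reference.  Strand typing never
appears on region nodes.  Ordered collections become `rdf:first`/
`rdf:rest` chains, unordered ones `rdfs:member` sets.

Blank nodes are never emitted.  Position and region nodes get
deterministic skolem IRIs built from their structural content key
(class, reference, coordinates, strand, percent-encoded).  Readable
content keys were chosen over opaque hashes: determinism and the
pre-merging effect are the same, no hashing dependency is needed, and
graph diffs stay human-readable.

The two reasoning rules the ontology relies on are implemented
procedurally, not through an OWL reasoner:

* **Reference materialization** (`materializeReferences()`): a lean graph
  may omit `reference` triples on positions; they are inferable by
  following a property chain from a record node that declares its primary
  sequence.  The exact chain predicates are configuration, not hard-coded
  truth: the default is one `location` hop followed by a closure over the
  structural predicates (list cells, membership, `begin`/`end`,
  `after`/`before`, `possiblePosition`), which reaches every position
  inside any location shape, including bare point positions.  The
  operation is idempotent and never removes statements, and the tests
  assert that query and validation results on a materialized graph equal
  those on an explicitly encoded one.
* **hasKey identity merge** (`mergeByKey()`): two exact positions with the
  same integer offset and the same reference (references equated by
  `owl:sameAs` count as the same) and the same strand typing are the same
  position.  All nodes sharing a key collapse onto the lexicographically
  smallest label — a deterministic choice that makes the merge confluent
  under statement reordering.  Differing strand typing keeps nodes apart:
  merging a forward-typed and an untyped position would manufacture a
  strand claim.

Turtle is the single concrete serialization (deterministic ordering:
sorted subjects, `rdf:type` first, sorted objects); the abstract
`TripleGraph` is available to other serializers.  The writer/parser cover
the profile the package emits; the test suite cross-checks round trips
against an independent RDF library on a small fixture.

## Conversion, validation and queries

Readers (`readGff3`, `readBed`, `readFeatureTable`, `readTurtleFeatures`)
are tolerant: malformed lines are skipped with line-level warnings in a
`ConversionReport`, never a hard stop.  INSDC feature tables carry no
topology header, so circular/length metadata comes from a sidecar mapping
(`references.tsv` in fixture bundles, `--refs` on the command line).
Writers are deterministic, and exports that lose information are always
flagged: fuzzy locations exported to interval formats become their
envelope plus a `lossy_fuzzy` attribute and a warning; mixed-strand
regions, which an interval row cannot hold at all, are reported and
skipped rather than flattened.  An untyped strand claim cannot survive an
INSDC string round trip — a plain `a..b` *means* forward strand in that
grammar — so reading back coerces absence to forward; this is the
format's convention, not an accident, and the tests pin it explicitly.

Validation is profile-based because the model is deliberately more
permissive than any single database: `core` checks structural sanity
(coordinates ≥ 1, both endpoints present, no contradictory strand typing,
one coordinate per exact position); `insdc` adds the same-reference rule
for region endpoints; `uniprot` pins every position to a designated
canonical sequence.  Profiles are monotone supersets of `core`, so
violation lists grow, never shrink, as profiles tighten.

Region-of-interest queries use a nested containment list (NCL) built over
normalized arcs: intervals sorted by start with ties broken by descending
end; an interval contained in its predecessor becomes a child, so each
level is containment-free and binary-searchable.  Overlap is closed-
interval intersection, strand-blind (strand filtering is a post-filter);
fuzzy features match when their envelope overlaps — "possible overlap"
semantics.  Wrapped features contribute one arc per segment and are never
duplicated in results; wrapped *queries* (`qmin > qmax` on a circular
reference) split at the origin and union.  Every query path is mirrored
by a naive linear scan (`roiQueryNaive`) kept as the oracle the index
must match exactly.

## The synthetic fixture generator

`generateFixtures()` renders one seeded feature population into all four
formats plus an arc manifest and the reference sidecar, so round-trip and
oracle tests share one ground truth.  Defaults: 10% of synthetic features
are origin-wrapping on circular references and 10% carry a fuzzy endpoint
— the mix the package's large-scale index test prescribes — on references
up to 100 kb, feature lengths 50–5,000 bases, strands drawn
forward/reverse/untyped at 45/45/10%.  Four worked examples are always
included deterministically: the cheY gene, the origin-wrapping Protein II
CDS, the forward/reverse convention pair at 1050..2080, and a
HindIII-style cut-site region with opposite-strand endpoints.

What the generator does *not* emulate: real nested gene models
(exon/intron hierarchies with parent links), remote-accession locations,
one-of positions in file input, and realistic coordinate clustering.
Passing tests therefore demonstrate convention correctness and structural
fidelity, not robustness to the full wildness of public flat files.

## Numerical and scale choices

All coordinates are R integers; the largest worked coordinate
(4,641,652) is far below the 32-bit limit.  Test problem sizes were
chosen to exercise the properties at meaningful scale while keeping the
default suite quick: 1,000-feature populations for the materialization,
round-trip and index/oracle suites, 1,000 random queries, 500 duplicated
features for the identity merge, and brute-force coordinate enumeration
capped at 10 kb references.  Determinism everywhere: fixed seeds in
tests, content-keyed node labels, sorted serializations, and fixture
bundles that are byte-identical for a given seed.

## Known limitations

* INSDC grammar coverage is the common core (points, ranges, fuzzy
  operators, `complement`, `join`, `order`, one level of remote
  accession); exotic legacy forms (nested compound-in-compound beyond
  `complement`, solitary `^` at sequence edges) are rejected with a
  parse error rather than guessed at.
* The Turtle parser reads the profile the package writes plus common
  N-Triples output; it is not a full Turtle 1.1 implementation (no
  collections syntax, no `@base`, no multi-line literals).
* Validation profiles implement the two database rule sets the model
  documents; further profiles are user configuration, not invention.
* The ROI index is in-memory and rebuilt per session; no persistence.
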