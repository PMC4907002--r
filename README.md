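# faldor

Strand-aware sequence feature locations in R: an S4 implementation of the
FALDO (Feature Annotation Location Description Ontology) model, with
bidirectional converters for the location dialects of GFF3/GTF, BED and
INSDC feature tables, RDF/Turtle emission and parsing, the model's two
reasoning rules, profile-based validation, circular-genome arithmetic and
fast region-of-interest queries.

## Who this is for

Anyone who has to move feature annotations between formats without
introducing off-by-one errors, or who publishes/consumes genomic
annotations as RDF: bioinformaticians integrating GFF/BED/GenBank data,
and developers of semantic-web resources that describe where features sit
on nucleotide or protein sequences.

## The model in brief

A **position** carries its own 1-based coordinate (counted from the 5' end
of the forward strand), its own reference sequence, and an optional strand
claim — `forward`, `reverse`, `both`, or no claim at all ("unknown strand"
is expressed by absence, never by a sentinel value). Positions may be
exact or fuzzy: in-range (`<n`, `>n`, `n.m`), one-of, or in-between
(`n^m`). A **region** is a pair of positions whose `begin` is the
*biological* start, so a reverse-strand gene has `begin > end`
numerically:

```
INSDC   complement(1965072..1965461)   biological start = 1965461
GFF3    start=1965072  end=1965461  strand=-   (start <= end, always)
BED     chromStart=1965071  chromEnd=1965461   (0-based, half-open)
length  end - start + 1 = 390 bp              (1-based inclusive)
```

Because strand and reference belong to positions, a region may legally
span two contigs or have endpoints on opposite strands (sticky-end cut
sites). On a circular replicon the single region `begin=6006, end=831`
replaces the INSDC split `join(6006..6407,1..831)`.

## Worked example

```r
library(faldor)

## the cheY gene from E. coli K-12, as written in its INSDC feature table
chey <- parseInsdc("complement(1965072..1965461)", "NC_000913.2")
coordinate(biologicalStart(chey))   # 1965461  (reverse strand: the 5'-most base)
regionLength(chey)                  # 390      (inclusive, 1-based)
regionToGff(chey)$start             # 1965072  (GFF wants start <= end)

## an origin-spanning CDS on the circular 6407 bp f1 phage genome
ref  <- ReferenceSequence("J02448", 6407, "circular")
join <- parseInsdc("join(6006..6407,1..831)", "J02448")
cds  <- collapseOriginJoin(join, ref)
coordinate(beginPosition(cds))      # 6006
coordinate(endPosition(cds))        # 831
regionLength(cds, ref)              # 1233     (= (6407-6006+1) + 831)

## RDF round trip
g <- emitTriples(list(FeatureRecord("cheY", chey, featureType = "gene")))
cat(substr(toTurtle(g), 1, 300))
recs <- parseTriples(fromTurtle(toTurtle(g)))
locationEqual(featureLocations(recs[[1]])[[1]], chey)   # TRUE

## region-of-interest query over a seeded fixture bundle
b   <- generateFixtures(tempfile(), n = 100, seed = 7)
idx <- buildRoiIndex(b$records, b$refs)
roiQuery(idx, "chr1", 2000, 2100)   # "fig2-forward" "fig2-reverse"
```

A command-line interface is installed with the package
(`inst/scripts/faldo`): `convert`, `validate --profile`, `roi`, `stats`
and `fixtures` subcommands over the same functions.

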