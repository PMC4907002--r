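Package: faldor
Title: Strand-Aware Feature Location Model with RDF Serialization
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Implements the FALDO (Feature Annotation Location Description
    Ontology) model of sequence feature locations as S4 classes: exact and
    fuzzy positions that carry their own strand and reference sequence,
    biologically oriented regions, and ordered or unordered region
    collections. Provides bidirectional converters for the location dialects
    of the major annotation formats (INSDC feature-table location strings,
    GFF3/GTF, BED), RDF emission and parsing with a deterministic Turtle
    serialization, procedural implementations of the position-identity
    (hasKey) merge and property-chain reference materialization rules,
    profile-based validation, circular-genome origin-spanning arithmetic,
    and region-of-interest overlap queries backed by a nested containment
    list index.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
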