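Package: sRNAmine
Title: Small RNA Sequencing Analysis and Plant miRNA Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale reimplementation of a plant small-RNA sequencing
    analysis pipeline: adapter clipping, quality and length filtering, and
    collapsing of raw reads into unique tags; classification of tags against
    reference RNA classes by perfect matching; discovery of novel miRNA
    candidates by mapping unannotated tags to expressed sequence tags,
    folding flanking contexts to minimum-free-energy hairpins, and applying
    miRNA/miRNA* duplex criteria; and miRNA target prediction with a
    point-based complementarity score (G:U wobble 0.5, mismatch 1.0, indel
    2.0, seed-region surcharge 0.5, 20-nt window minimum, accept below 3.0).
    A seeded synthetic-data module generates reference sets, EST collections
    with planted hairpin precursors, read libraries, and transcripts with
    planted target sites of controlled defect composition, so every stage is
    testable against known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
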