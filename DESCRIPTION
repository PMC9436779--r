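Package: fgfr2trunc
Title: Detection and Interpretation of FGFR2 Exon-18-Truncating Alterations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Classifies DNA structural variants, copy-number profiles,
    small somatic variants and RNA splice-junction evidence into FGFR2
    exon-18 (E18) truncation categories. Implements six rearrangement
    types with exon-phase reading-frame prediction, full-length and
    E1-E17 partial amplification calling under WGS-, GISTIC-, cell-line-
    and panel-style rule sets, hotspot and C-terminal truncating mutation
    classification, alternative last-exon usage quantification, cohort
    integration with incidence arithmetic, and co-occurrence /
    mutual-exclusivity enrichment statistics (proportion Z-tests,
    Fisher's exact tests, Benjamini-Hochberg correction). A synthetic
    cohort generator with planted ground truth makes every stage
    testable without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    jsonlite
Config/testthat/edition: 3
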