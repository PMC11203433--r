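Package: exonmut
Title: Exon-Wise Sequence Comparison, Variant Naming and Mutation Hotspot
    Detection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Compares per-exon nucleotide sequences against a coding
    reference by global pairwise alignment with affine gap penalties, calls
    and 3'-normalizes substitutions, deletions and insertions in cDNA (c.)
    coordinates, and aggregates cohorts of samples into per-exon mutation
    histograms, position recurrence tables and sliding-window hotspot
    intervals. Includes a seeded synthetic-cohort generator that plants
    variant catalogues into synthetic references, and a command-line
    interface for the compare/cohort/simulate workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    graphics,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
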