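Package: methfootprint
Title: Tracking Genome-Wide Footprints of Targeted DNA Methyltransferases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for quantifying on-target and off-target activity of
    dCas9-methyltransferase fusion proteins from bisulfite sequencing methylation
    calls. Implements fixed-width genome tiling with coverage filters, paired
    per-tile t-tests with Benjamini-Hochberg adjustment and dual significance
    thresholds, methylation-matched off-target background selection, time-course
    gain curves, top-k tile overlap, CpG-island class summaries, H3K4me3 density
    scoring, read-level hemimethylation classification, and local polynomial
    smoothing of methylation tracks. Includes a strand-resolved synthetic
    methylome and bisulfite-call simulator emulating a methylation-depleted,
    maintenance-competent cell system, so every analysis stage can be validated
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
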