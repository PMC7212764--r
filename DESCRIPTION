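Package: crzscan
Title: Promoter Scanning for CRZ1/CDRE-Type Binding Sites with Empirical
    Null Calibration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate calcineurin-dependent response elements
    (CDREs, the binding sites of CRZ1-family zinc-finger transcription
    factors) in fungal promoters. Extracts fixed-length regions upstream of
    annotated translation starts from a genome and GFF3 annotation, scores
    both strands with a position weight matrix in log2-odds against a
    background model, normalizes scores by the matrix maximum, and calls
    sites above a threshold that can either be fixed (0.8 by default) or
    calibrated against an empirical null built from shuffled or i.i.d.
    control sequences. Includes a synthetic promoter-set generator with a
    known planted-site truth table for end-to-end validation, per-gene
    sense/antisense site maps, and relative qPCR quantification by the
    2^-ddCt (Livak) method with reference-gene normalization and a
    calibrator condition.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    methods,
    graphics,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
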