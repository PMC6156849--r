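Package: eventscope
Title: Cross-Platform Detection and Quantification of Alternative Splicing Events
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects and classifies alternative splicing events from per-gene
    splicing graphs built from transcript annotation (GTF) or from observed
    junction and coverage tables. Each event consists of two mutually
    exclusive paths plus a shared reference path. Percent-spliced-in (PSI)
    is estimated per sample by penalized non-negative least squares on
    linear-scale path signals, with a relative-error diagnostic for the
    additive signal model. Differential splicing is tested per path with
    voom/limma moderated linear models combined by an opposite-sign
    fold-change rule, with Storey pi0/FDR estimation and binomial read
    thinning for depth analyses. Events detected on two platforms (e.g.
    RNA-seq and junction microarrays) are matched through genomic
    containment and overlap of their path footprints. A seed-deterministic
    synthetic-data generator produces annotation, junction counts and path
    signal matrices for validation without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
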