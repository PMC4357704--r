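Package: oritime
Title: Replication-Timing Chromatin Enrichment and DNA Combing Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for DNA-replication-origin firing studies:
    replication-timing-resolved histone-mark coverage distributions with a
    one-sided two-sample Kolmogorov-Smirnov comparison against input DNA,
    molecular DNA combing statistics (fork velocity, inter-origin distance,
    replication-figure classification with Mann-Whitney and chi-square
    tests), ChIP-qPCR percent-input quantification, relative BrdU
    fluorescence and H3-normalized densitometry. Includes a synthetic-data
    generator (origin-firing genome model, Repli-Seq-like timing profiles,
    ChIP/input coverage, dual-pulse IdU/CldU fiber sets, qPCR Ct tables and
    cytometry intensities) so every analysis stage is testable without
    external downloads, plus readers and writers for bedGraph, fiber TSV and
    Ct CSV formats and a reproducible pipeline runner with run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
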