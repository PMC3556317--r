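Package: heteroseq
Title: Hybrid-Parent Trio RNA-Seq Analysis of Expression Heterosis
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of bulk RNA-seq from a hybrid and its two
    parents (an F1 trio): RPKM quantification, negative-binomial exact tests
    for differential expression with Benjamini-Hochberg FDR, estimation of
    composite additive and dominance effects per gene with classification of
    the dominance ratio (potence) into above-high-parent, high-parent-level,
    mid-parent-level, low-parent-level and below-low-parent expression
    patterns, mid-parent and high-parent heterosis statistics for replicated
    trait phenotypes, hypergeometric term enrichment, hierarchical sample
    clustering, and overlap of candidate genes with QTL marker intervals.
    Includes a negative-binomial trio simulator with known ground truth so
    every stage is testable without external data, and a command-line
    pipeline driver.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    optparse,
    ape,
    S4Vectors,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer
Config/testthat/edition: 3
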