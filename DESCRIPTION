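Package: medipdmr
Title: Differential DNA Methylation Analysis for Two-Colour MeDIP Tiling Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for comparative two-channel MeDIP-chip promoter
    tiling arrays: GC-binned loess normalization of M values and A-quantile
    normalization across arrays, 600 bp sliding-window median smoothing,
    empirical-normal probe statistics computed per pair of comparative
    hybridizations, intersection of per-pair significant sites, clustering of
    consecutive same-sign significant probes into differentially methylated
    regions (DMRs) with intensity and CpG-density filters, a cutoff-based
    differential-expression filter for pooled expression arrays, and
    integration statistics linking DMRs to differentially expressed genes
    (expected random overlap, megabase-scale gene-cluster scan, chromosome
    plot tables). Includes a synthetic two-colour tiling-array and expression
    generator with planted ground truth so the full chain is testable without
    hybridization data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
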