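Package: poolpin
Title: Two-Dimensional Pooled Sequencing Design, Variant Calling and Sample Deconvolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and analysis of two-dimensional (row-by-column) pooled
    resequencing experiments for rare-variant detection. Samples are arranged
    into matrices and pooled by row and by column, so that every sample is
    sequenced in exactly two pools. The package builds and queries pooling
    layouts, calls variants in each pool from pileup-style base counts using
    depth, start-point-bias and allele-fraction thresholds, classifies each
    variant across the pools of a matrix as pinnable, multiple, singleton or
    missing-coverage, deconvolves pinnable variants back to individual
    carriers at row-column intersections, and aggregates results across
    matrices. A synthetic pooled-sequencing generator with known genotype
    truth makes the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
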