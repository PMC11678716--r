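Package: chromloops
Title: Distance-Stratified Chromatin Loop Candidates and Low-Affinity
    Binding-Site Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts distance-stratified candidate chromatin loops between
    transcription-factor-bound Capture-C baits and targets, scores anchor
    regions with a position-specific affinity model (top-k low-affinity
    window reporting), and profiles candidate regions against differential
    chromatin accessibility classes and histone-mark peak sets. Includes
    genomic interval arithmetic (intersect, window, coverage, incremental
    distance stratification), peak and gene-model readers with peak-location
    classification, nonparametric statistics (Wilcoxon rank-sum, Fisher
    exact, Pearson correlation, Benjamini-Hochberg adjustment), and a seeded
    synthetic-data generator that emits a complete input bundle with planted
    ground truth so every stage of the analysis is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
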