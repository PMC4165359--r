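Package: fungimeth
Title: Downstream Analysis of Fungal Whole-Genome Bisulfite Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the downstream computational analysis of fungal
    whole-genome bisulfite sequencing (WGBS) experiments in repeat-rich
    genomes: strand-aware per-cytosine methylation calling in CG, CHG and
    CHH contexts, feature-level methylation profiling of genes and
    transposable elements (meta-plots, size strata, gene-proximity
    profiles), a z-score based feature-level differential-methylation
    caller, read-depth copy-number-variation detection between two
    samples, the composite RIP (repeat-induced point mutation) index from
    dinucleotide frequencies, RPKM-based methylation-expression
    association analyses, and a seeded synthetic-data generator that
    emulates a transposon-rich genome with bimodal CG methylation for
    validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    methods,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
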