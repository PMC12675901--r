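Package: degronseq
Title: Spike-In Calibrated Nascent RNA-Seq Analysis of Acute Transcription Factor Depletion
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative analysis of acute transcription-factor depletion time courses
    measured by spike-in-calibrated nascent RNA-seq. Provides interval counting over
    genes and enhancers, spike-in median-of-ratios size factors robust to global
    transcriptional shutdown, negative-binomial Wald differential expression with
    Benjamini-Hochberg adjustment, de novo transcript-unit calling from stranded
    coverage with enhancer-RNA designation and proximity-based target assignment,
    ChIP-seq occupancy classification of super-enhancers and typical enhancers, and
    the set-intersection logic that nominates putative direct targets. A deterministic
    synthetic-data generator emulates the full study design so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
biocViews: Transcriptomics, GeneRegulation, DifferentialExpression, Normalization,
    Epigenetics, FunctionalGenomics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
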