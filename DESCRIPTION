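Package: tscdyn
Title: Transcriptome and Methylome Dynamics of Trophoblast Stem Cell Derivation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for trophoblast stem cell (TSC) derivation
    time courses profiled under natural fertilization (NF), nuclear transfer
    (NT) and Scriptaid-treated nuclear transfer (SNT). Implements dynamic
    gene selection from principal-component loadings with six-cluster trend
    classification, a transcription-factor panel pseudotime with a
    random-panel resampling null, CpG-island methylation aggregation from
    bisulfite CpG calls with progressive (PHIM) and aberrant (AHM/ALM)
    methylation calling, rescue and donor-origin accounting, promoter
    CpG-density classes, and set-overlap enrichment statistics
    (hypergeometric test, representation factor, over-representation score).
    Includes a synthetic-data generator that plants the expression and
    methylation structures the analysis assumes, with truth tables for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    BiocGenerics,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
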