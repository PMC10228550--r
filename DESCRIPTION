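Package: fragMRD
Title: Cell-Free DNA Fragmentomics for Minimal Residual Disease Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects minimal residual disease (MRD) after curative resection of
    non-small cell lung cancer from whole-genome cell-free DNA (cfDNA)
    fragmentation profiles. Implements fragment ingestion and coverage
    downsampling, fragment size ratio (FSR) feature extraction over genomic
    bins with GC-bias correction, elastic-net penalized Cox modeling with
    leave-one-out cross-validated risk scores and a specificity-constrained
    MRD cutoff, tumor-informed ctDNA variant filtering with a normal-pool
    background test, combined calling, and the full evaluation suite
    (exact binomial confidence intervals, ROC/AUC, hazard ratios, lead time).
    A synthetic cohort generator emulating nucleosome-patterned fragment
    length mixtures and tumor-fraction-driven hazards makes the whole
    pipeline testable without controlled-access patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Rsamtools,
    rtracklayer,
    glmnet,
    survival,
    pROC,
    splines,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Software, Survival, Classification, Sequencing, Epigenetics
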