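Package: survGSEA
Title: Survival-Based Gene Set Enrichment Analysis
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Ranks genes by Cox proportional-hazards log hazard ratios
    estimated from RNA-seq expression and censored survival data, and tests
    gene sets for enrichment at the extremes of that ranking with a
    permutation-calibrated weighted running-sum statistic. Also provides a
    standard fold-change-based enrichment mode driven by a negative binomial
    GLM, an outcome-permutation false discovery rate audit, tools to compare
    survival-based and fold-change-based results, reporting helpers, and a
    synthetic-data generator emulating a TCGA-like renal carcinoma cohort so
    the whole pipeline is testable offline.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    limma,
    MASS,
    SummarizedExperiment,
    S4Vectors,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    survival,
    fgsea,
    DESeq2
biocViews: GeneSetEnrichment, Survival, Pathways, RNASeq, Transcriptomics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
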