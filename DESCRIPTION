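Package: cfAneuploidy
Title: Chromosome-Arm Aneuploidy Scoring and Biomarker Validation for
    Cell-Free DNA
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements the mFAST-SeqS genome-wide aneuploidy score for
    shallow LINE-1 amplicon sequencing of plasma cell-free DNA: per-arm
    read counting from SAM/BAM, library-size normalization, a healthy
    control reference panel with leave-one-out calibration, per-arm
    Z-scores and the genome-wide sum-of-squares statistic dichotomized at
    the established cut-off of five. Also provides the biomarker
    validation layer used to compare the score against circulating tumor
    cell counts and clinical outcome: concordance cross-tabulation,
    Spearman correlation, Jonckheere-Terpstra trend test, Mann-Whitney,
    chi-square, Kaplan-Meier estimation, log-rank tests including a
    1-df trend version, and Cox proportional-hazards regression with a
    univariable screen and backward stepwise selection. A synthetic
    cohort generator (Dirichlet-multinomial arm counts under a
    tumor-fraction mixture model, correlated CTC counts, proportional
    hazards outcomes) supports end-to-end validation without patient
    data.
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
    SummarizedExperiment,
    Rsamtools,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: CopyNumberVariation, Sequencing, Survival, StatisticalMethod
RoxygenNote: 7.3.3
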