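Package: methscreen
Title: Methylome-Based Preimplantation Embryo Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Scores preimplantation embryos from whole-genome bisulfite
    CpG methylation calls. Combines a whole-genome methylation-level
    deviation score calibrated through a binomial GLM with a
    promoter-signature gradient-boosted classifier (TSS-score) that
    includes iterative noisy-label cleaning, and evaluates retrospective
    embryo selections with heterogeneity (H-index), selection-status
    (S-index) and discriminability (DI) statistics. Ships a synthetic
    cohort simulator so every stage is testable without clinical data,
    promoter epimutation calling against a birth-group baseline, and an
    end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
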