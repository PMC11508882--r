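Package: pgseval
Title: Polygenic Score Evaluation and Transferability Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate polygenic risk scores (PGS) in case-control
    cohorts with internal population structure. Reads PGS-Catalog-format
    scoring files, harmonizes score variants against cohort genotypes
    (strand-flip resolution, ambiguous-variant policy, coverage reporting),
    computes weighted-dosage scores, and runs a full transferability
    evaluation: distributional tests between cases and controls,
    covariate-correlation screens, percentile-stratified adjusted odds
    ratios, Boruta feature selection, logistic risk models with repeated
    cross-validation, DeLong comparison of ROC areas, and analyses
    stratified by geographic subpopulation. A Balding-Nichols
    synthetic-cohort generator with a known genetic and covariate truth
    supports end-to-end validation without access to individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
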