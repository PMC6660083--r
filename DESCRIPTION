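Package: metscreen
Title: Case-Control Metabolomics Screening, Pathway Impact, Diagnostic
    Panels and Correlation Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native pipeline for targeted serum metabolomics
    case-control studies. Computes control-referenced Z-scores from raw
    intensities, screens metabolites by partial least squares discriminant
    analysis (PLS-DA) variable importance in projection (VIP) combined with
    Mann-Whitney U tests, aggregates hits into pathway "metabolic impact"
    and fold-enrichment tables, builds and validates sparse (1-6 metabolite)
    diagnostic panels with repeated double cross-validation and permutation
    testing, compares per-group metabolite correlation networks
    (differential interactome coupling), and partitions each subject's
    extreme metabolites into shared diagnostic versus individualized
    abnormalities. Includes a seeded synthetic cohort generator with
    pathway-structured covariance and planted effects so every stage is
    testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
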