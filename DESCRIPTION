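Package: plasmanet
Title: Plasma Metabolomic Diagnostic Models and Correlation-Network Topology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for peripheral-blood targeted-metabolomics
    case-control studies: detection filtering with half-minimum imputation,
    per-analyte two-group screening with an equal-variance gate (Student's t
    versus Mann-Whitney U), cross-validated LASSO logistic screening followed
    by backward stepwise logistic modelling with an odds-ratio-based
    collinearity elimination rule, ROC evaluation (rank AUROC, Youden cutoff,
    predictive values), Pearson-threshold correlation networks with a full
    topological parameter battery (clustering coefficient, density,
    heterogeneity, degree centralization, shortest paths, assortativity,
    greedy modularity), and Kaplan-Meier/log-rank survival verification.
    Includes a synthetic-cohort generator with log-normal concentrations,
    planted group effects and group-specific block correlations for
    exercising the pipeline when patient-level data are unavailable.
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
    glmnet,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    igraph,
    pROC,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
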