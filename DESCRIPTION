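Package: imputebench
Title: Benchmarking Missing-Value Imputation for Affymetrix Expression Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for evaluating missing-value imputation on
    MAQC-style Affymetrix expression data. Generates seeded probe-level datasets
    with the MAQC factorial structure (reference-RNA pools, sites, replicates),
    makes Present/Marginal/Absent detection calls via exact one-sided Wilcoxon
    signed-rank tests on discrimination scores, filters to complete expression
    matrices, summarizes probe sets with ideal-mismatch Tukey-biweight
    summarization and trimmed-mean scale normalization, deletes entries at
    random, imputes with ten methods (row average, KNN, SVD, local least
    squares, least squares adaptive, Bayesian PCA, NIPALS), scores imputations
    with four error measures (RMSE, LRMSE, RAE, RAE-L2), and aggregates
    per-cell ranks into an overall method ranking.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
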