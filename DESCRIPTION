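Package: nephroscape
Title: Autoencoder Profiling of Kidney Involvement in Lupus Registry Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for unsupervised profiling of kidney involvement in
    systemic lupus erythematosus (SLE) from registry-style survey data.
    Implements curation of 75-item clinical survey records (deduplication,
    range-based repair of erroneous laboratory values, complete-case
    filtering, rule-based kidney-involvement classification), a
    three-dimensional autoencoder embedding of the curated feature matrix,
    contribution-rate attribution via analytic partial derivatives of the
    encoder, and sliding-window two-proportion association scans over the
    latent feature plane. A synthetic-cohort generator with planted subgroup
    structure, injectable duplicates, erroneous entries and missingness makes
    the whole pipeline testable without access-restricted registry data.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
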