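Package: temposel
Title: Temporal Tests of Selection from Paired Seedling and Seed Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects viability selection acting within a single growing season
    from paired genotype samples taken at the seedling stage and at seed
    maturity. Provides signed allele-frequency-change G-tests, drift-corrected
    temporal F_ST outlier tests against empirical (multi-allelic marker based)
    and simulated (Wright-Fisher) null distributions, pseudo-likelihood
    estimation of the effective population size from temporal change at
    neutral markers, and approximate Bayesian computation of the selection
    coefficient under a viability-selection model with dominance. Includes a
    synthetic-data generator emulating a multi-site, two-year field design so
    the whole inference chain can be exercised against known truth, and a
    pipeline that orchestrates all stages with reproducible seeding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
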