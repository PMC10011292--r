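Package: maltgerm
Title: Preharvest Sprouting, Germination Dynamics and Malting Quality Genetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Quantitative-genetic analysis of the relationship between preharvest
    sprouting (PHS) resistance and malting quality in spring barley breeding
    populations. Provides germination percentage and germination-index statistics
    from plate counts, a restricted maximum likelihood (REML) engine for the
    Gaussian mixed-model family used in multi-environment malting trials
    (technical repeatability, line-by-timepoint variance partitioning with a
    check-based plot-error decomposition, across-year heritability), fixed-effect
    line BLUEs, bivariate REML genetic correlations across after-ripening
    timepoints and within HvMKK3 dormancy-allele groups with likelihood-ratio
    tests, correlated response to selection with per-cycle genetic variances,
    config-driven end-use quality scoring, and a synthetic breeding-population
    generator with a pleiotropic major dormancy locus for simulation-based
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
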