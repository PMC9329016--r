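Package: comorbnet
Title: Phenotype-Stratified Comorbidity Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds bootstrap-validated multimorbidity networks from binary
    comorbidity cohorts stratified by clinical phenotype. Provides pairwise
    disease association statistics (phi coefficient, co-occurrence relative
    risk, chi-square/Fisher tests, Clopper-Pearson prevalence intervals),
    within-stratum fixed-size bootstrap resampling with a percentile edge
    rule, network density and node-connectivity comparisons across strata,
    and a latent-Gaussian synthetic cohort generator with exact marginal
    prevalence control and direct pairwise phi targeting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pracma,
    yaml
Config/testthat/edition: 3
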