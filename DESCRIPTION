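Package: medimr
Title: Two-Sample and Two-Step Mediation Mendelian Randomization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) from GWAS,
    pQTL and eQTL summary statistics: reading, validation and allele
    harmonization of summary-statistics tables; instrument selection by
    significance, minor-allele-frequency and greedy LD clumping, with a
    cis-window restriction for molecular QTL exposures; causal-effect
    estimation by Wald ratio, fixed- and multiplicative-random-effects
    inverse-variance weighting, MR-Egger regression and the weighted
    median; sensitivity diagnostics (Cochran's Q, Egger intercept,
    MR-PRESSO global and outlier tests, leave-one-out); and two-step
    mediation MR with delta-method confidence intervals for the indirect
    effect and the proportion mediated. A synthetic three-trait
    summary-statistics generator with known causal structure, horizontal
    pleiotropy, LD blocks and allele-encoding hazards supports end-to-end
    testing and calibration without access to external GWAS repositories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
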