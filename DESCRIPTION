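Package: mrflow
Title: Two-Sample and Multivariable Mendelian Randomization from GWAS
    Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) on GWAS
    summary statistics: reading and validating per-variant association
    tables, selecting instrumental variants (genome-wide significance,
    LD clumping, minor-allele-frequency filtering, proxy lookup,
    F-statistic instrument-strength metrics), harmonizing exposure and
    outcome effects onto a common effect-allele frame, univariable
    estimators (Wald ratio, inverse-variance weighted, MR-Egger,
    weighted median, weighted mode) with heterogeneity and pleiotropy
    diagnostics, MR-PRESSO outlier detection and correction,
    multivariable MR for joint direct effects of correlated exposures,
    false-discovery-rate control across a study grid, and a synthetic
    summary-statistics generator with known causal truth for
    calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
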