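Package: mrkit
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 1.0.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization with GWAS summary
    statistics: reading and harmonizing exposure/outcome association tables,
    two-stage pleiotropy screening (Bonferroni confounder screen; Cochran's Q
    with I2, MR-Egger intercept, MR-PRESSO), the inverse-variance-weighted,
    weighted-median and MR-Egger causal estimators with odds-ratio reporting,
    instrument-strength (R2, F) and binary-outcome power analysis, and a
    synthetic summary-statistic generator with known causal effect and
    configurable horizontal pleiotropy. Ships the 162-variant educational
    attainment instrument table used to study ischemic stroke risk.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
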