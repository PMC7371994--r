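Package: strokemr
Title: Two-Sample Mendelian Randomization for Stroke and Alzheimer's
    Disease Summary Statistics
Version: 0.1.0
Authors@R: person("strokemr", "maintainers", email = "strokemr@example.org",
    role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization from GWAS summary
    statistics: reading and validating summary tables, allele harmonization
    with palindromic-SNP and proxy handling, instrument selection rules,
    inverse-variance weighted / weighted-median / MR-Egger causal estimators,
    Cochran's Q heterogeneity, Steiger directionality filtering, leave-one-out
    and single-SNP sensitivity analyses, a staged pleiotropy screen with
    Bonferroni correction, and a synthetic summary-statistic generator for
    calibration studies. Ships the published instrument tables for four stroke
    phenotypes (any stroke, any ischemic stroke, large-artery atherosclerotic
    stroke, cardio-embolic stroke) against Alzheimer's disease as packaged
    fixtures.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
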