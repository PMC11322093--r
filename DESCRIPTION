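Package: netmr
Title: Network Mendelian Randomization with GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization from GWAS summary
    statistics: reading, validation and allele harmonization of summary
    tables; instrumental-variable selection with significance and
    minor-allele-frequency filters, greedy LD clumping, outcome-association
    exclusion and Steiger directionality filtering; a suite of causal-effect
    estimators (inverse-variance weighted, maximum likelihood, weighted
    median, MR-Egger, MR-PRESSO, debiased IVW, contamination mixture,
    robust adjusted profile score, and constrained maximum
    likelihood with model averaging); sensitivity analyses (Cochran's Q,
    Egger intercept, leave-one-out, reverse MR) with an evidence-tier
    classifier; multivariable MR; two-step (network) mediation analysis with
    delta-method intervals; and a reproducible synthetic GWAS
    summary-statistics generator for end-to-end offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
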