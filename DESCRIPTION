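Package: pancanstrat
Title: Gene-Centric Pan-Cancer Expression Stratification and
    Genomic-Instability Analysis
Version: 0.1.0
Authors@R:
    person("Pan-Cancer Stratification", "Contributors", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Tools for stratifying multi-cohort tumour datasets by the
    expression of a focal gene and characterising the molecular and clinical
    correlates of the resulting high/low groups. Provides readers for
    cBioPortal-style tab-separated exports (expression, mutation, per-sample
    metrics, clinical tables, GMT gene sets, driver-gene lists), quartile
    stratification with nonparametric group comparisons, cross-cohort Spearman
    co-expression consistency voting, per-tumour-type driver-mutation
    delta/ratio enrichment, proliferation-adjusted linear models of
    genomic-instability metrics with attenuation summaries, Kaplan-Meier and
    log-rank survival comparisons, and a seeded latent-factor simulator that
    generates multi-cohort datasets with a planted mediation structure so
    every stage of the pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
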