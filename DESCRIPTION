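Package: nhanesaudit
Title: Audit Pipeline for Formulaic Single-Factor Survey-Database Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for meta-research audits of corpora of published
    single-factor association studies built on cyclical health surveys
    such as NHANES. Harmonizes heterogeneous significance evidence
    (reported p-values, possibly censored as "<x", or odds ratios with
    confidence intervals) into two-sided p-values, applies group-wise
    step-up false-discovery-rate re-correction (Benjamini-Yekutieli and
    Benjamini-Hochberg) implemented from first principles, builds the
    bipartite predictor-condition association multigraph with degree
    summaries and dual-role detection, audits analyzed year windows
    against a survey-cycle availability calendar to flag selective data
    usage, and generates fully synthetic corpora with known ground truth
    for calibration experiments contrasting uncorrected single-factor
    analysis with jointly corrected analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
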