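Package: kmopt
Title: Hazard Ratio Recovery from Kaplan-Meier Plots Anchored on the
    Published P Value
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the Kaplan-Meier life table underlying a published
    two-arm survival plot from digitized (time, survival) points, the starting
    numbers at risk and the published log-rank P value, by solving for the
    unknown per-interval censor counts with sequential quadratic programming
    (SLSQP) anchored on the chi-square statistic implied by the P value. Emits
    the log hazard ratio ln(HR) and its variance for use in aggregate-data
    meta-analysis, supports exact and non-exact ("<0.01", "ns") P values, and
    includes a synthetic individual-patient-data simulator with exact
    product-limit and log-rank oracles plus Monte-Carlo tooling for deciding
    how many curve points to extract and where to place them.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    nloptr,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
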