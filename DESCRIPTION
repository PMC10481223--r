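Package: milksense
Title: Milk Conductivity Sensing, Maturation Scoring, and Normative
    Reference Charts
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for tracking human milk secretory activation from
    handheld conductivity measurements. Converts raw conductance readings
    to per-device-calibrated, temperature-corrected conductivity, maps
    conductivity to a 0-100 milk maturation percent (MM%) score, applies
    rule-based retrospective breastfeeding-status classification, builds
    day-postpartum normative percentile reference charts with
    day-matched smoothing windows, flags scans against a percentile
    threshold, and quantifies group separation (two-way ANOVA with Tukey
    contrasts) and threshold sensitivity. A seedable synthetic cohort
    simulator with group-dependent activation kinetics makes the whole
    pipeline testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
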