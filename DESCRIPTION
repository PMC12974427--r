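Package: hes1dyn
Title: Single-Cell HES1 Oscillation Dynamics and Cell Cycle Reentry Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-cell HES1 protein reporter
    time-series in proliferative, CDK4/6-inhibitor-arrested, released and
    HES1-misexpressing breast cancer cells. Provides band-isolating
    moving-average detrending, Lomb-Scargle and autocorrelation periodicity
    estimation with circadian-level (20-30 h) and ultradian (4-8 h) band
    power statistics, mitosis-to-mitosis pseudo-time alignment, dip/peak
    event detection, dual-reporter phase relations, quiescence-reentry and
    division-fraction statistics, together with a calibrated synthetic
    cohort generator that emulates each experimental regime so every
    quantification can be exercised without the original imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    graphics,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
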