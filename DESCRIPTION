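Package: scscea
Title: Cost-Utility Modelling of 10 kHz Spinal Cord Stimulation for Chronic Back and Leg Pain
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Decision-analytic model comparing 10 kHz high-frequency spinal cord
    stimulation (SCS) with non-rechargeable and rechargeable low-frequency SCS for
    chronic back and leg pain from a UK NHS perspective. A six-month decision tree
    (screening trial, permanent implantation, response and complication branching,
    early explants) feeds a six-state Markov cohort model run in 3-month cycles to a
    15-year horizon with device replacement, explants, transient complications,
    reoperation and all-cause mortality. Provides deterministic cost-consequence and
    cost-utility analysis (ICER and dominance), one-way (tornado) sensitivity
    analysis, threshold search, named scenario analyses, probabilistic sensitivity
    analysis with beta/gamma parameter sampling and cost-effectiveness acceptability
    curves, and a synthetic patient-level trial generator with input re-estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
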