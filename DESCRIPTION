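Package: racirkit
Title: Rapid A-Ci (RACiR) Curve Correction and FvCB Model Fitting for
    Large-Chamber Gas Exchange
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for processing rapid CO2-response (RACiR) measurements
    made with large gas-exchange cuvettes, such as conifer needle chambers.
    Recomputes assimilation, transpiration, conductances and intercellular
    CO2 from raw infrared gas analyzer channels (so leaf area can be
    corrected after measurement), isolates the quasi-linear steady-state
    portion of a CO2 ramp with a delta-threshold rule, corrects leaf curves
    with empty-chamber polynomials selected by BIC, and fits the
    Farquhar-von Caemmerer-Berry model to obtain Vcmax, Jmax and dark
    respiration. Includes a first-order chamber-mixing simulator that
    generates realistic instrument logs for testing the whole pipeline.
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
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
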