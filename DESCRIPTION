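Package: ojip
Title: JIP-Test Analysis of Fast Chlorophyll Fluorescence Transients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing fast chlorophyll a fluorescence induction
    (OJIP) transients in plant and algal stress physiology. Extracts the
    canonical O, K, J, I and P fluorescence markers from induction traces,
    derives the full set of JIP-test parameters (quantum yields, specific
    energy fluxes per reaction centre and the performance index PI_abs),
    computes non-photochemical quenching from dark/light fluorescence pairs,
    summarises oxidative-stress assay panels (OFR, MDA, SOD, POD, CAT), and
    compares treatments against a control condition with Welch tests, percent
    changes and significance flags. A calibrated synthetic-data generator
    simulates a two-strain by three-temperature replicated design so the whole
    pipeline can be exercised and tested without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    grDevices,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
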