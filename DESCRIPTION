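Package: cbfclock
Title: Model Selection for Circadian Control of CBF3 Transcription
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the Arabidopsis circadian clock shapes
    the daily waveform of CBF3 (DREB1A) transcription. The package simulates
    clock-regulator time courses under different photoperiods and genotypes,
    defines a Hill-function transcription submodel for CBF3 mRNA, enumerates
    an ensemble of thirteen candidate regulatory architectures, fits each
    architecture to multi-photoperiod expression time series by seeded
    multi-start least squares, ranks the ensemble by corrected AIC with
    Akaike weights, and runs in-silico experiments (clock-mutant fold
    changes and circadian gating of cold pulses) that discriminate among
    architectures. A synthetic-data generator emulates the statistical
    structure of diurnal CBF3 microarray series, and an optional SBML import
    path can drive the clock stage from a published ODE model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
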