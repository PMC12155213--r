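Package: rrsburn
Title: Resonance Raman Spectroscopy Analysis of Burn Wound Depth
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Decomposes 441 nm resonance Raman spectra of burn wounds into a
    smooth fluorescence baseline and weighted hemoglobin/mitochondria reference
    libraries, computes healthy-skin-normalized Hemoglobin and Fluorescence
    Indices as perfusion biomarkers, applies robust (ROUT-style) outlier
    screening, categorizes wounds by burn depth with time-to-heal and
    histology quality-control rules, and evaluates ROC-based burn-depth
    classifiers. Includes a synthetic-data module that simulates whole
    multi-depth porcine burn studies (pseudo-Voigt spectral libraries,
    polynomial fluorescence, frame noise, cosmic spikes) so that every stage
    of the pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stats,
    utils,
    generics,
    ggplot2,
    readr,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
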