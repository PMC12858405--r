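Package: chromoswitch
Title: Modelling Ideal Efficacy Photoswitches and Wavelength-Controlled Pharmacology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Tools for modelling azobenzene photopharmacology from per-isomer
    absorption spectra to receptor-level bioactivity. Computes photostationary
    states and time-resolved E/Z isomer fractions under arbitrary illumination
    protocols, couples them to competitive two-isomer receptor occupancy with an
    operational (Black-Leff) transduction model supporting inverse agonism and
    receptor reserve, classifies photoswitches as affinity or efficacy switches,
    simulates cycling and wavelength-scan experiments with FLIPR-like or
    electrophysiology-like readouts, fits Hill dose-response curves and rival
    affinity/efficacy action-spectrum models with AIC comparison, and generates
    seeded synthetic datasets calibrated to published photostationary-state
    anchors for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
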