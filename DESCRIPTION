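Package: lipidmech
Title: Thermomechanical Characterisation of Model Lipid Membranes from DSC and AFM Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for qualifying minimal bacterial inner-membrane
    lipid models. Extracts melting temperatures and transition enthalpies from
    differential scanning calorimetry thermograms with polynomial baseline
    correction and a nonlinear scan-rate extrapolation to thermodynamic
    equilibrium; fits AFM nanoindentation force curves with a finite-thickness
    (thin-film) Hertz contact model to obtain the Young's modulus of supported
    lipid bilayers; detects membrane breakthrough (rupture) events; classifies
    force-map pixels into pre- and post-transition phases and computes
    phase-resolved statistics; derives the area stretching modulus via thin
    plate theory; and measures patch thickness from AFM topography. Includes
    seeded synthetic-data generators with embedded ground truth so that every
    analysis stage can be validated in a closed loop.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    MASS,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
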