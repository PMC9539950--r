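Package: uhdrICE
Title: Ion Collection Efficiency of Micro Ionization Chambers in
    Ultra-High Dose-Rate Pulsed Electron Beams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Determination of the ion collection efficiency (ICE) of a micro
    ionization chamber under ultra-high dose-rate (UHDR) pulsed electron
    beams, as used in FLASH radiotherapy dosimetry. Provides
    radiochromic-film reference dosimetry (degree-5 polynomial calibration of
    dose versus net optical density), a TRS-398-style chamber dose equation
    with temperature-pressure correction, saturation-charge anchoring by a
    through-origin linear fit at low dose-per-pulse, logistic
    recombination-model fitting per pulse duration, and GUM-style Monte-Carlo
    uncertainty propagation for the saturation slope and the fitted-curve
    envelope. A synthetic beam/detector generator emulates a pulsed
    experimental linac session (shot-to-shot output variation, beam-current
    transformer monitoring, film noise components, depth-dose transfer
    factors) so the full pipeline is testable end-to-end without
    experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
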