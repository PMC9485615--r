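Package: vmhsim
Title: Virtual MEG Helmet Simulation and Source-Localization Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation framework for virtual magnetoencephalography (MEG)
    helmets: composite magnetometer arrays assembled from rigid
    counter-movements of a whole-head 248-channel array. Provides a
    three-layer spherical source grid with tangential dipole bases, the
    closed-form spherical-conductor forward model with gain matrices and
    effective-rank measurement, a Monte-Carlo-calibrated technical/brain
    noise model, a sequential equivalent-current-dipole inverse solver,
    helmet evaluation with a count-over-distance precedence scheme and
    neighbor-robustness metric, and drivers for helmet comparison,
    robustness assessment, and three-stage prior-based helmet
    personalization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
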