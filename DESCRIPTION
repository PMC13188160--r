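Package: dermdecon
Title: Dimensionless Modelling of Dermal Decontamination Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models the fate of a finite dermal dose of a toxicant (chemical
    warfare agent or industrial chemical) competing between inward diffusion
    through the stratum corneum, surface loss by evaporation and interfacial
    reaction, and bulk neutralization by a reactive decontaminant. The system
    is reduced to two dimensionless groups, a Damkohler number Da and a
    surface-loss number pi_surf, and solved analytically by eigenfunction
    expansion of the reaction-diffusion slab with a Robin boundary at the
    exposed surface and a perfect sink at the viable epidermis. Provides
    closed-form steady-state mass partitioning, transient mass-fraction
    curves, effective time constants and the decontamination window, kinetic
    regime classification, Da/pi_surf absorption risk maps, an independent
    finite-difference cross-check solver, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
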