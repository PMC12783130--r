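Package: minfluxsim
Title: Realistic Simulation of MINFLUX Localization Microscopy Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A comprehensive simulator for MINFLUX single-molecule
    localization and tracking experiments. Models patterned-excitation
    scanning with analytic and vectorial (Debye-integral) point spread
    functions including phase masks, aberrations, pinhole detection and
    bead convolution; single-fluorophore photophysics (blinking, bleaching,
    photon budgets, diffusion and stepping motion); closed-form and
    iterative least-squares and maximum-likelihood position estimators
    suitable for FPGA deployment; Abberior-style sequence execution with
    scouting, iterative zoom-in, center-frequency-ratio and photon quality
    checks and scanner dead times; and an analysis layer with numerical
    Cramer-Rao bounds, RMSE/STD/bias decomposition, flicker variance
    analysis and MSD-based diffusion estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
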