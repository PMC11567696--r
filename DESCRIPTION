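Package: diffrate
Title: Diffusive Association and Adsorption Rate Models for Dilute Solutions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Forward prediction and inverse geometry estimation for the family
    of diffusion-limited association/adsorption rate equations used in
    single-molecule binding kinetics: hard-sphere collision theory, the
    Smoluchowski steady-state rate, the Langmuir-Schaefer transient rate, and
    discrete nearest-neighbor-reshuffle models of fractional reaction order
    (2/3, 4/3, 5/3 in concentration). Includes Stokes-Einstein transport
    utilities, a dimensional-analysis model registry, log-log reaction-order
    fitting with S3 fit objects, per-concentration model inversion tables,
    a seeded Brownian-dynamics Monte Carlo engine that validates the
    closed-form diffusion results (Gaussian propagator, first passage,
    absorbing-sphere flux, mean exit times), a synthetic power-law dataset
    generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
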