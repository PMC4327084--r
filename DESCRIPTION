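Package: thermofield
Title: Stationary Thermal Field Design for Heated Transcutaneous
    Oxygen-Sensor Matrices
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models the stationary temperature field produced by a square
    plane resistive heater combined with a supplemental O-ring wire heater
    at the interface of two semi-infinite media (air above, biological
    tissue below), as used to thermostat multichannel transcutaneous
    oxygen-sensor matrices. Provides the interface Green's-function field
    kernels of both sources (adaptive quadrature and analytic closed
    forms, including the complete-elliptic-integral ring solution),
    superposition on surface grids, isotherm extraction, quantitative
    homogeneity metrics for the central sensing zone, a min-max heater
    balance optimizer, a JSON-configured command-line interface and a
    seeded fixture generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
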