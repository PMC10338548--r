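Package: condensim
Title: Phase-Field Simulation of Transcription-Driven Nuclear Condensates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates active nuclear condensates as a conserved phase-field
    (Model B) protein concentration coupled to an actively transcribed,
    diffusing and degrading RNA species on a two-dimensional circular domain.
    Transcriptional activity is modelled as one or more spatially clustered
    (Gaussian) rate-constant fields or as a uniform control. Includes a
    five-equation two-phase coexistence solver for the bulk free energy and
    re-entrant partition scans, condensate morphometrics (effective radius,
    vacuoles, interface counting via the free-energy Hessian, centroid,
    eccentricity, directed-flow velocity), a closed-form modified-Bessel
    theory for steady-state RNA gradients around an active transcription
    site, and scenario drivers with parameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
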