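Package: follE2
Title: Estradiol Production Modelling for Bovine Ovarian Follicles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models estradiol (E2) production during the bovine estrous cycle
    from ultrasound follicle-tracking data. Converts follicle diameters into
    granulosa-layer volumes via closed-form shell geometry and a fitted
    quadratic, derives an IGF1 surrogate from progesterone (P4), classifies
    follicles into recruited/secondary/dominant/atretic-dominant classes with
    a 90% atresia rule, and simulates a Hill-regulated ordinary differential
    equation for E2 with distinct healthy and atretic production terms.
    Includes weighted nonlinear least-squares parameter identification,
    Bayesian uncertainty quantification by adaptive random-walk Metropolis
    sampling with credible regions and prediction bands, local sensitivity
    analysis via a scaled Jacobian, and a seeded synthetic estrous-cycle
    generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
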