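Package: ovawalk
Title: Random-Walk Modelling of Ovarian Reserve Decay and Age at Natural
    Menopause
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Models the loss of dormant primordial follicles from the human
    ovarian reserve as a first-passage problem for a drifted random walk of
    per-follicle Integrated Stress Response activity between a growth
    threshold and a death threshold.  Provides the closed-form
    (inverse-Gaussian-type) expected decay curve, exact discrete-walk
    simulators and lattice occupancy propagation, population simulation of
    age-at-natural-menopause distributions under log-normal starting-supply
    heterogeneity, subject-variable and time-variant drift, acute-loss
    interventions, least-squares parameter estimation on log follicle
    counts, and a small command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
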