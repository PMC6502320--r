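Package: dualcapture
Title: Two-Source Capture-Recapture Estimation for Disease Surveillance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates the size of a disease population from two overlapping
    surveillance case lists. Links case records across sources into capture
    histories, computes the Lincoln-Petersen and Chapman closed-form
    estimators with Wald intervals, a covariate-stratified estimator, and a
    Bayesian closed-population Mt model fitted by data-augmentation Markov
    chain Monte Carlo with convergence diagnostics. Derives source
    completeness and prevalence rates from census denominators, and ships a
    synthetic surveillance generator with stratum-specific capture
    probabilities and controllable source dependence so the full pipeline is
    testable without confidential patient data.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
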