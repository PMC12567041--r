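Package: ascipbpk
Title: Whole-Body Physiologically Based Pharmacokinetic Simulation of
    Asciminib
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonlinear whole-body physiologically based pharmacokinetic
    (PBPK) simulation of the BCR::ABL1 inhibitor asciminib, built around a
    permeability-limited liver with saturable BCRP-mediated biliary efflux.
    Provides a compound-parameter library with unit conversions, a synthetic
    virtual-population generator with hepatic (Child-Pugh) and renal
    impairment physiology, retrograde translation of pathway fractions
    (fm/ft/fe) into enzyme-level kinetic parameters, an ODE engine with
    dynamic drug-drug-interaction modifiers (reversible inhibition,
    time-dependent inactivation, induction turnover), mechanistic-static
    interaction metrics (Net Effect AUC ratio, R3, relative induction
    score), a virtual clinical-trial simulator with paired-arm geometric
    mean ratios, and predictive-performance statistics (prediction error,
    AFE, AAFE, GMFE, twofold and 25 percent bounds, Guest criteria).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
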