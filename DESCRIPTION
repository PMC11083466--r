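Package: lfncsim
Title: Simulated Oxygen Delivery by Low-Flow Nasal Cannula in Small Infants
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico twin of a mechanical infant breathing simulator for
    studying the effective fraction of inspired oxygen (FiO2) delivered by
    low-flow nasal cannula. Models multi-breath gas mixing in an upper-airway
    dead-space reservoir coupled to a well-mixed lung compartment under
    continuous cannula flow, to steady state. Provides the classical
    closed-form effective-FiO2 estimators (Benaron-Benitz, Finer, the
    STOP-ROP convention) with a blender-correction equation, power-law
    fitting of FiO2 against minute ventilation, formula-bias evaluation with
    exact rank-sum testing, and predictive FiO2 lookup charts over infant
    weight and respiratory rate.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
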