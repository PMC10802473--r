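Package: hsrkit
Title: Modeling and Analysis of Heat Shock Response Feedback Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Deterministic ODE modeling of the Hsf1-Hsp70 heat shock response
    circuit in budding yeast, with a core expression feedback loop (Hsf1
    induces Hsp70; Hsp70 represses Hsf1) and an auxiliary feedback acting
    through productive release of Hsp70 from unfolded clients. Includes
    residual-sum-of-squares fitting of strain-specific reporter time courses
    (single-parameter release-rate fits for auxiliary feedback mutants and
    two-parameter re-calibration for ethanol stress), regulon-wide reporter
    kinetics (logistic fits, fold-change normalization, PCA, induction-rate
    versus timing tradeoff), Hill dose-response analysis (EC50/IC50),
    flow-cytometry summary statistics with side-scatter normalization,
    growth-curve rate extraction, and seeded synthetic-data generators that
    emulate the statistical structure of single-cell reporter libraries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
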