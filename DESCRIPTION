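Package: biomarkergame
Title: Eco-Evolutionary Dynamics of Functional Cancer Biomarkers Under Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Models cell-cell competition among cancer cells that differ in
    production of a functional biomarker, using a fitness-generating
    (G-function) framework coupled to Lotka-Volterra population dynamics.
    Provides evolutionarily stable strategy (ESS) solvers and pairwise
    invasibility plots under chemotherapy and biomarker-targeted therapy,
    numerical integration of the coupled ecological-evolutionary equations,
    fixed and threshold-triggered (adaptive) treatment schedules including
    sequential evolutionary-trap protocols, and experiment drivers that
    quantify the bias of total-biomarker readouts, compare protocol
    effectiveness, and sweep thresholds and sensitivity parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
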