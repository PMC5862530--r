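Package: cropflow
Title: Multi-Scale Analysis of Collective Food Intake in Ant Colonies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing how ant colonies regulate collective food
    intake through individual crop loads. Provides a canonical event-log data
    model for trophallactic interactions, food-source feedings and per-ant
    crop-load timelines; an agent-based colony simulator in which interaction
    volumes are exponential random fractions of the recipient's available crop
    space and forager nest exits are triggered at fixed crop-unload increments
    by a crop-only logistic rule; colony-scale analyses of the negative
    feedback between colony satiation and food inflow (per-forager flow fits,
    foraging-cycle statistics, perturbation response); interaction-scale fits
    of the conditional exponential volume law and its collapse under
    available-space normalization; and forager exit-decision analysis under
    three candidate decision-rate models with k-nearest-neighbour exit
    probability surfaces and logistic fits.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    graphics,
    tools,
    utils,
    minpack.lm,
    deSolve,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
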