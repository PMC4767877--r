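Package: treebrowse
Title: Browse-Induced Tree Mortality from Herbivore Feeding Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Mechanistic modelling of tree mortality caused by folivorous
    herbivores in mixed forests. Couples an individual-tree foliage
    production/loss model (with analytic intake and mortality thresholds) to
    a size-biased negative-binomial model of herbivore feeding events, so
    that annual mortality probabilities can be predicted from routine canopy
    monitoring data (foliage cover index, foliar browse index, stem
    diameter). Includes calibration of species growth parameters from
    tagged-tree panels, maximum-likelihood site initialisation from
    single-visit surveys, prediction of mortality by canopy-cover class,
    management curves of mortality against a herbivore trap-catch index, and
    a seeded synthetic-data generator for end-to-end parameter-recovery
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
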