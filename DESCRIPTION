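Package: treeislandr
Title: Analysis of Tree-Island Restoration Experiments in Oil-Palm Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of tree-island enrichment
    experiments embedded in oil-palm plantations: construction of random-
    partition experimental designs and seeded synthetic datasets, Hill-number
    diversity with rarefaction, threshold-based multidiversity and
    multifunctionality with correlation-cluster indicator pre-selection,
    per-island oil-palm yield-change accounting (spillover, remain-change and
    foregone components), allometric above-ground biomass and other derived
    ecosystem-function indicators, principal-component vegetation-structure
    axes, and treatment/mediation inference via linear mixed-effect models and
    piecewise structural equation models with d-separation tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    emmeans,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    optparse
Config/testthat/edition: 3
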