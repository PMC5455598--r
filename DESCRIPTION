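Package: elncut
Title: Examined Lymph Node Count, Nodal Staging Accuracy, and Survival
    Cut Point Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the number of examined lymph nodes (ELN)
    at cancer resection relates to nodal stage migration and overall
    survival. Implements a Bayes/hypergeometric model of occult nodal
    disease (the probability that a declared node-negative patient harbors
    undetected positive nodes), adjusted per-ELN-count odds-ratio and
    hazard-ratio effect series from logistic and Cox proportional hazards
    models, LOWESS smoothing of those series, Chow-test structural-break
    scanning to locate an ELN cut point, and validation of a dichotomized
    threshold. A mechanistic synthetic-registry generator (latent nodal
    population, hypergeometric node sampling, proportional-hazards survival
    with an occult-disease mortality penalty) makes the full pipeline
    testable without access to restricted registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
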