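Package: morbimap
Title: Multimorbidity Relationship Maps for Neurodevelopmental Impairments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for multimorbidity analysis of neurodevelopmental cohorts:
    per-instrument impairment classification across 20 test domains (Touwen
    neurological examination, MABC-2, SIPT, NEPSY-II), per-child impairment
    burden profiles, thresholded co-occurrence relationship maps, and the
    accompanying statistical layer (contingency odds ratios with FDR control,
    bootstrapped t-tests, wild-bootstrap regression with BCa intervals,
    cumulative-logit odds ratios). Includes a calibrated synthetic-cohort
    generator with a group-shifted latent liability so the full pipeline is
    testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
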