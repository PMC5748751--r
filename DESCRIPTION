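Package: flavperm
Title: Caco-2 Permeability Analytics and Structure-Permeability Modelling
    for Flavonoids
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis of bidirectional flavonoid transport across Caco-2
    cell monolayers and quantitative structure-permeability (QSPR)
    modelling.  Computes apparent permeability coefficients, efflux
    ratios with transport-mechanism classification, cellular-accumulation
    ratios, solvent-stability and mass-balance quality checks, and fits
    descriptor-based permeability models by ordinary least squares or
    NIPALS partial least squares with stepwise descriptor selection,
    collinearity filtering, leave-one-out cross-validation and external
    test-set validation.  Ships a transcription of a published 30-compound
    flavonoid permeability study as a packaged dataset, plus seeded
    synthetic-data generators with the same statistical structure for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
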