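Package: sapgrow
Title: Sapwood-Driven Biomass Growth of Tropical Canopy Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs aboveground biomass growth and whole-tree traits
    (sapwood area, total leaf area, sapwood lifespan, wood density) of
    tropical canopy trees from stem-disc, wood-sample and branch field
    measurements, and fits the associated trait-based growth models:
    all-subsets regression with delta-AIC model averaging and
    Akaike-weight variable importance, a full sapwood-area model,
    species-centered path analysis, and regression imputation of sapwood
    area for species without a visible sapwood boundary. Ships a
    calibrated synthetic field-data generator with known ground truth for
    validating the whole pipeline by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
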