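Package: cranberrydx
Title: Compositional Nutrient Diagnosis and Carryover Yield Prediction for
    Cranberry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Factor-specific nutrient diagnosis of cranberry (Vaccinium
    macrocarpon) tissue tests on the compositional simplex, and prediction of
    current- and next-year berry yield from local features. Tissue analyses of
    ten nutrients are closed to 1000 g/kg with a filling value and handled with
    log-ratio geometry: centred log ratios, isometric log ratios under a
    sequential binary partition, Aitchison distances, and perturbation vectors
    that rank nutrients as relative shortage or excess. A random-forest
    classifier about a yield cutoff partitions specimens into confusion-matrix
    quadrants; true-negative (high-yielding, nutritionally balanced) specimens
    form the reference bank for nearest-neighbour local diagnosis, regional
    average diagnosis, and quartile concentration ranges. A lagged panel links
    current-year composition, fertilization and yield to next-year yield to
    capture carbohydrate and nutrient carryover, with predictive diagnosis
    against the next-year reference bank. Includes a seeded synthetic-data
    generator emulating the multi-site, multi-year survey structure the
    analysis assumes, so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    pROC,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
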