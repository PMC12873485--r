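Package: npiscore
Title: Nutrient Profile Model Scoring and Healthfulness Classification for
    Food-Marketing Content Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements the UK 2004/05 Nutrient Profile Model (NPM) scoring
    system and its linear rescaling to the Nutrient Profile Index (NPI,
    -2 x NPM + 70, healthy at NPI >= 64), together with the supporting
    machinery used in content analyses of food and beverage marketing:
    per-100 g normalisation of nutrition facts, the first-five-ingredients
    fruit/vegetable/nut assumption, a configurable product taxonomy with
    restaurant and children's-drinks beverage categories, nutrition-source
    resolution with explicit omission reasons, brand-stratified descriptive
    summaries, and a calibrated synthetic corpus generator for end-to-end
    testing of the pipeline without access to original video data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
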