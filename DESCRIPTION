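Package: lakesav
Title: Lake Trophic State, Light-Limited Submerged Vegetation, and Manatee
    Habitat Suitability Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing shallow tropical lakes as habitat for
    herbivorous aquatic megafauna. Summarises station water chemistry into
    zone means, nutrient-limitation calls (TN/TP ratio) and Carlson trophic
    state indices; models underwater light with the Lambert-Beer law using
    the Poole-Atkins Secchi-depth proxy for the attenuation coefficient;
    extrapolates water clarity across a lake from the distance to its
    outlet; predicts light-limited submerged aquatic vegetation (SAV) on a
    bathymetric raster and validates the prediction against sonar-derived
    biovolume with a confusion matrix (accuracy, sensitivity, specificity,
    precision, Matthews correlation coefficient); and simulates seasonal
    water-level recession to map depth-based habitat suitability. Includes
    a seeded synthetic-lake generator so the full pipeline is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
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
    broom,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
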