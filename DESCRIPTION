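Package: paddythresh
Title: Region-Specific Soil Thresholds for Cadmium and Arsenic in Paddy
    Soil-Rice Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Derives region-specific soil environmental thresholds for
    cadmium and arsenic in neutral-to-alkaline paddy fields from paired
    soil-rice survey data. Fits log10-scale multiple linear transfer
    models of grain metal concentration on soil properties (with
    correlation screening and variance-inflation-factor collinearity
    control), inverts them at food-safety limits to obtain safety
    thresholds (ST), fits logistic species-sensitivity distributions to
    reciprocal bioconcentration factors to obtain hazard thresholds (HT)
    at the 95 percent protection level, and evaluates any threshold
    system by four-quadrant misclassification analysis and three-class
    soil-quality assignment. Includes a calibrated synthetic generator
    of paired soil-rice datasets for karst high-geochemical-background
    regions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
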