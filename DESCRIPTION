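Package: odsensor
Title: Colorimetric Sensor Array Analysis for Monitoring Yeast Cell
    Concentration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for quantitative monitoring of cell concentration
    during Saccharomyces cerevisiae culture from colorimetric
    (olfactory-visualization) sensor arrays.  The package extracts
    per-spot RGB difference features from paired before/after images of
    a 4x3 dye array, fits a back-propagation neural network regressor
    mapping color features to optical density (OD600), and performs
    wrapper feature selection over the 36 color components with ant
    colony optimization scored by a weighted mean absolute deviation
    objective, including the repeated-run frequency protocol used to
    choose a reduced sensor.  A synthetic-data module simulates the
    full study design (growth curves, dilution-corrected OD
    measurement, sensor responses, and rendered array images) so the
    entire pipeline is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
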