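Package: foveametry
Title: Foveal Pit Morphometry from OCT Segmentation Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures the central retina of cynomolgus monkey eyes from
    per-B-scan semantic segmentation maps produced by optical coherence
    tomography (OCT) image segmentation. Cleans label maps of enclosed
    segmentation artifacts, extracts and smooths the internal limiting
    membrane surface across the raster, localizes the deepest foveal point
    (the nulla), and derives a 21-parameter thickness and area profile per
    eye. Includes a parametric synthetic foveal-pit phantom with analytic
    ground truth for end-to-end validation, and a reference-database
    statistics battery (grouped summaries with boxplot statistics, Pearson
    correlations, principal component analysis, two-way MANOVA with Wilks'
    lambda, and per-coefficient two-way ANOVA with Bonferroni-adjusted
    significance categories).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    grDevices,
    tools,
    png,
    EBImage,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    car,
    optparse
Config/testthat/edition: 3
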