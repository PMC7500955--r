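Package: centriomorph
Title: Nanoscale Centriole Morphometry for Ultrastructure Expansion Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of expanded-centriole fluorescence images:
    expansion-factor calibration and unit conversion, radial mapping of
    protein shells relative to the microtubule wall from top views,
    longitudinal length/coverage and diameter measurements from lateral
    views, roundness and microtubule-wall integrity assessment, confocal
    foci counting and intensity normalization, and 1-D decoration
    periodicity estimation. Ships a synthetic expanded-centriole image
    generator with ground-truth manifests so that every measurement stage
    can be validated by parameter recovery, together with the
    nonparametric and parametric group statistics used to compare
    experimental conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
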