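Package: gelcorr
Title: Pixel-by-Pixel Correlation Analysis of 2D Gel Electrophoresis Image Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Headless pixel-by-pixel correlation analysis of two-dimensional gel
    electrophoresis (2DE) image stacks. Loads stacks of grayscale gel images via a
    CSV manifest, aligns them to a reference with 4-parameter similarity transforms
    (rotation, uniform scale, translation) with missing-data tracking, normalizes
    each image (mean, median or z-score), and computes per-pixel Spearman rank
    correlation against an external per-sample variable together with a normalized
    standard deviation map and significance maps from a correlation t-test or an
    (exhaustive or Monte Carlo) permutation test. Composite "biosignature" product
    maps (correlation x significance x variance) highlight gel regions that respond
    strongly, significantly and substantially to the external variable. Includes
    rectangular region-of-interest summaries, full-precision text export, heat-map
    rendering, a synthetic gel-stack generator with known ground truth, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    jsonlite,
    e1071,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
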