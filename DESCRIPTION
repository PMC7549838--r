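Package: lilymorph
Title: Theoretical Morphological Modelling of Water-Lily Flowers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates three-dimensional water-lily (Nymphaea) flowers from a
    16-parameter theoretical morphological model combining piecewise-linear
    organ size gradients, spiral phyllotaxis with golden-angle divergence, and
    interpolated tepal elevation angles. Supports theoretical morphospace
    sweeps over parameter grids, orthographic silhouette projection with
    convex-hull shape descriptors (solidity and convexity), measurement of
    scanned floral-organ sheets by moment-based ellipse approximation, and
    recovery of model parameters from ordered organ measurements by linear
    regression. Includes synthetic-data generators (measurement tables, organ
    sheets, and shape-class cohorts) so the full pipeline can be exercised
    without access to specimen scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
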