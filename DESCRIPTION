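Package: effbw
Title: Effective Bandwidth of Spatial Smoothing Splines
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the spatial scale implied by including a given
    number of unpenalized thin-plate regression splines in a regression
    model. Builds the nested spline basis and its projection smoothing
    matrix for any planar point set and computes the effective bandwidth:
    the median, over locations, of the smallest distance at which a
    location's smoothing weight turns negative (a minimum smoothing
    radius), together with the original loess-based average-radius
    variant. Bandwidths can be swept over degrees of freedom and reported
    as tables and plots. Includes rectangular grid generation, clipping of
    grids to polygons (GeoJSON or plain vertex lists), CSV coordinate
    input, seeded subsampling, and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ggplot2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
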