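Package: soilscape
Title: Landscape-Scale Geostatistics and Variance Partitioning for Soil
    Microbial Communities
Version: 0.1.0
Authors@R:
    person("Soilscape", "Developers", email = "soilscape@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the spatial structure of soil bacterial and
    archaeal communities sampled on a landscape-scale grid.  Provides
    rank-order (normal-scores) ordinary kriging with Matern variograms fitted
    by weighted least squares or maximum likelihood, model validation by
    leave-one-out standardized squared prediction errors with simulation-based
    confidence limits, weighted UniFrac dissimilarity and non-metric
    multidimensional scaling with permutation-based vector fitting, principal
    coordinates of neighbour matrices (PCNM) spatial eigenvectors, and
    variance partitioning of taxon abundances and community dissimilarity
    among soil, land-management and spatial predictor blocks (partial
    regression and distance-based redundancy analysis).  A synthetic landscape
    generator emulates a square sampling grid with infill sites, correlated
    Matern soil fields, contiguous land-management clusters and compositional
    taxon tables, so that the whole pipeline can be exercised and calibrated
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
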