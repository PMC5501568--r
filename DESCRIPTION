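Package: somzones
Title: Terrain-Based Zone Delineation and Soil Microbial Sampling Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Delineates within-field management zones from terrain and
    apparent electrical conductivity (EMI) data and derives a stratified
    soil sampling scheme from them.  A gridded elevation model is turned
    into slope, aspect and plan curvature; EMI transects are interpolated
    to the grid by inverse distance weighting; the per-location feature
    vectors are clustered by a sequentially trained self-organizing map
    followed by K-means on the codebook; and one best-matching field
    location per cluster (plus spatially spread additional sites) is
    selected for sampling.  Companion routines compute soil microbial
    indicators (chloroform-fumigation biomass C and N, carbon and
    nitrogen mineralization rates, mass-specific rates) and the
    associated statistics: attribute-indicator correlations, one-way
    ANOVA by cluster with Tukey HSD letters, and one-sample t-tests of
    cluster members against their representative site.  A synthetic
    field generator with planted zone structure supports power analysis
    and end-to-end validation of the sampling design.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    readxl
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
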