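Package: marshmussel
Title: Bivalve-Augmented Salt-Marsh Ecogeomorphic Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulator of sediment deposition and vertical
    accretion in a tidal salt-marsh creekshed engineered by filter-feeding
    bivalves (ribbed mussels). Couples a depth-averaged shallow-water solver
    with wetting and drying and vegetation-dependent Chezy friction to a
    suspended-sediment advection-diffusion model with settling, and adds an
    implicit mussel filtration sink that converts filtered sediment to
    biodeposits on mussel mounds. Includes tidal harmonic synthesis with
    quartile-based spring-neap classification and representative-window
    selection, a synthetic rectangular creekshed domain builder, a scenario
    engine for crossed vegetation and mussel-cover experiments with
    multi-scale aggregation, survey-scaling calculators (creekhead areal
    coverage, creekshed mussel coverage, mound-height elevation estimation,
    settling-velocity fitting from suspended-sediment decay), and seeded
    synthetic fixtures for all inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
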