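Package: rafttrap
Title: Elastic Kinetic Traps in Lipid Domain Coalescence
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Continuum-elasticity analysis of the interaction between
    liquid-ordered and liquid-disordered lipid domains in planar bilayers.
    Minimizes a quadratic tilt-splay-stretching energy functional for two
    registered domains approaching across a gap, extracts the
    fusion-opposing energy barrier from the interaction profile, converts
    barriers into per-collision merger probabilities through the Derjaguin
    approximation and a Boltzmann kinetic model, estimates merger
    probabilities with binomial uncertainty from collision tallies, maps
    quaternary lipid mixtures onto phase compositions and
    composition-weighted spontaneous curvatures, and provides a seedable
    generator of synthetic collision streams and coalescing domain
    populations for testing the estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
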