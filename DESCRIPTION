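Package: lineascape
Title: Lineage Delimitation, Distribution Modelling and Reserve Design for
    Island Faunas
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An integrated workflow for intraspecific conservation planning on
    islands: single-threshold general mixed Yule-coalescent (GMYC) lineage
    delimitation on ultrametric trees (maximum-likelihood and Bayesian MCMC
    variants), presence-background maximum-entropy distribution modelling with
    replicate evaluation and minimum-training-presence thresholding,
    geostatistical interpolation of lineage occurrence from genetic distance
    matrices by ordinary kriging, species and lineage richness mapping, gap
    analysis against a zoned protected-area plan with log-linear representation
    targets, and target-based greedy reserve prioritization with boundary
    length penalties and cell costs.  A synthetic-data module generates trees,
    genetic distances, landscapes, virtual species and zoning plans with the
    statistical structure the analyses assume, so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
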