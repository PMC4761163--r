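Package: phyloniche
Title: Phyloclimatic Modeling of Ecological Niche Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing niche conservatism and divergence across a
    time-calibrated phylogeny from presence-only distribution data. Fits
    maximum-entropy ecological niche models (linear + quadratic features)
    over gridded environmental layers, computes Schoener's D and Warren's I
    niche overlap with niche-identity and background-similarity
    randomization tests, builds predicted niche occupancy (PNO) profiles
    and Brownian-motion ancestral tolerance reconstructions, and
    characterizes temporal patterns of niche evolution via age-range
    correlation, disparity-through-time curves with the MDI statistic, and
    phylogenetic PCA / MANOVA. Includes a synthetic-data generator
    (spatially autocorrelated environmental surfaces, pure-birth trees,
    niches evolving under Brownian motion or Ornstein-Uhlenbeck regimes)
    so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phytools,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
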