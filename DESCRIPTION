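Package: beehexagon
Title: Floral Color Diversity, Assembly and Phylogenetic Signal in Bee Color Space
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps floral reflectance spectra (300-700 nm) into the hexagon
    color space of trichromatic hymenopteran vision (von Kries adaptation to a
    leaf-green background, photon-flux-corrected daylight illumination,
    A1 visual-pigment nomogram receptors) and summarizes community-level color
    signaling: minimum-convex-polygon color diversity with rarefaction,
    mean-pairwise-distance assembly tests against richness-preserving
    randomization nulls (color and cophenetic distances, SES and permutation
    p-values), and phylogenetic signal of hue and chromatic contrast via
    Blomberg's K and Mantel matrix permutation tests. Includes a synthetic-study
    generator (spectral archetypes, Yule trees, Brownian trait evolution,
    structured community draws) so the full pipeline is testable without field
    data, and a configuration-driven driver that writes the standard result
    tables with seeds and a run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    picante,
    phytools,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
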