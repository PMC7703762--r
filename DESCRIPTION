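Package: epigraphr
Title: Graphlet-Based Quantification of Epithelial Tissue Organization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the organization of packed epithelial tissues from
    segmented label images. Builds the cell-to-cell contact network, counts
    the 73 automorphism orbits of the connected 2-5-node graphlets for every
    interior cell, and compares tissues through the graphlet degree
    distribution agreement distance (GDD). Each tissue is embedded as a
    three-coordinate point (Epi-Hexagons, Epi-Random, Epi-Voronoi5) -- its
    GDD to a regular hexagonal lattice, a random Voronoi tessellation and a
    five-times Lloyd-relaxed Voronoi diagram -- and placed on a reference
    scale of noisy centroidal Voronoi tessellations (the CVTn path), with an
    outlier test that classifies the tissue as conforming to or deviating
    from that scale. Includes generators for hexagonal, random-Voronoi, CVT
    and CVTn tessellations rasterized as label images.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    png,
    tiff,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
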