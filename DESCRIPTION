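Package: pjones
Title: Multi-Scale and Persistent Jones Polynomials for Curves in 3-Space
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantifies the entanglement of collections of open or closed
    polygonal curves in 3-space with a sphere-averaged Jones polynomial
    computed from linkoid projections and a Kauffman bracket state sum with
    segment cycles.  Localizes the invariant in two ways: a multi-scale
    characteristic matrix of Jones values over distance shells around each
    curve segment, and a persistent Jones polynomial that weights the facets
    of a Vietoris-Rips filtration with Jones values and compares the
    resulting barcodes through a weighted bottleneck distance.  Includes
    protein applications: alpha-carbon B-factor feature extraction with
    Lasso regression and secondary-structure barcodes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    glmnet,
    graphics,
    grDevices,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
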