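Package: vesselmorph
Title: Edge-Based 3D Vessel Segmentation and Vascular Morphometry for
    Phase-Contrast Microtomography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Segments the three-dimensional vasculature of unstained,
    paraffin-embedded tissue imaged by propagation-based phase-contrast
    X-ray microtomography, where vessel lumens are inconsistently hyper-
    or hypo-intense and intensity thresholding fails.  The segmentation
    core combines dual-scale 3D median filtering with recursive
    Deriche-Canny edge detection and morphological post-processing
    (island removal, closing, hole filling).  Downstream morphometry
    provides topology-preserving 3D thinning skeletonization, branch
    pruning, vessel volume fraction, shrinkage-corrected vessel length
    density, local-thickness diameter maps, geodesic seed-based vessel
    classification, and largest-inscribed-sphere maximum diameters.  A
    synthetic vessel-phantom generator with known centerline/radius
    ground truth makes every stage testable without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    png
Config/testthat/edition: 3
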