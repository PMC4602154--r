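Package: trabgeo
Title: Trabecular Bone Geometry from 3-D Binary Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measurement of rod- and plate-like geometry in 3-D binary voxel
    images of trabecular bone. Implements the structure model index (SMI) by
    surface-mesh dilation together with its decomposition into positive and
    negative components and the concave surface fraction (CF), the ellipsoid
    factor (EF) by maximal inscribed ellipsoid fitting seeded from the medial
    axis, bone volume fraction (BV/TV), an erosion-based simulator of bone
    resorption, and the regression and rank-test machinery used to study the
    confounding of SMI by BV/TV. Includes analytic voxel phantoms (sphere,
    cylinder, plate, rod-plate lattice, pseudo-trabecular noise) so every
    measurement is testable without external image data, multi-page TIFF
    stack I/O, and PLY export of curvature-class colored surface meshes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
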