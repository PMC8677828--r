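Package: edgeup
Title: 3D Edge Enhancement and Super-Resolution Upsampling for Small
    Brain Structures in MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-based edge enhancement with 2x super-resolution
    upsampling for small, low-contrast structures in volumetric MRI,
    such as the lateral geniculate nucleus. Local structure is modelled
    as the faces, edges and vertices of a polyhedron: a precomputed
    library of binary 1-, 2- and 3-plane templates is fitted to every
    voxel neighbourhood by closed-form least squares, the best-fitting
    template's high-resolution core is substituted for the voxel, and
    shifted-grid signal averaging suppresses noise between fitting
    passes. Includes exact cube-phantom rasterization with controlled
    partial volume, Gaussian noise injection, half-maximum segmentation,
    Dice and volume-recovery metrics, and runners for noise-sweep and
    iteration-convergence experiments, plus NIfTI region-of-interest
    input/output and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
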