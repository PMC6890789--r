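Package: clarityatlas
Title: Structure-Tensor Tractography, Cell Segmentation and Atlas
    Connectivity for Cleared-Brain Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational core of a multimodal cleared-brain/atlas
    integration workflow. Estimates local fiber orientation from 3D
    structure tensors, propagates deterministic FACT streamlines with an
    angular stopping criterion, and maps tract density and streamline
    terminal zones. Segments nuclei and neurons with a marker-controlled
    3D watershed after Phansalkar local thresholding, voxelizes
    segmentations onto atlas grids, and summarises features per
    hierarchical atlas region. Interrogates projection-connectivity
    tables with parent-fallback experiment lookup, ontology depth/order
    filtering and common-target ranking, flags cellular degeneration
    along the connectivity tree, locates cut tissue sections inside
    whole-brain volumes by recursive similarity search, and provides
    group-level statistics (sum-of-squares heat-maps, label-wise paired
    t-tests, voxelwise Spearman correlation, landmark registration
    error) and along-tract profiles with hemisphere-asymmetry tests.
    Ships deterministic synthetic phantom generators (fiber tubes, blob
    fields, toy atlases) with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    tibble,
    tiff,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
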