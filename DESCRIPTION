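Package: arterylabel
Title: Anatomical Labeling of Intracranial Arteries from Angiographic Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline for voxel- and segment-wise anatomical
    labeling of intracranial arteries from 3-D angiographic volumes (e.g.,
    time-of-flight MR angiography) plus a binary vessel mask. Implements the
    detailed (26-class) and aggregated (13-class) Circle-of-Willis label
    constellations, topology-preserving 3-D skeletonization with radius
    encoding, bifurcation-based segment decomposition, stratified
    cross-validation with dual-scale patch extraction and rotation
    augmentation, a multi-scale encoder-decoder voxel classifier with a
    context path and deep supervision (trained with Adam and categorical
    cross-entropy), a random-forest voxel baseline, softmax segment washing,
    and macro-F1 / balanced-accuracy evaluation at voxel and segment level.
    Ships a synthetic cerebrovascular phantom generator so the whole pipeline
    is exercisable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    igraph,
    ranger,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
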