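Package: wscalp
Title: Brain Extraction from T1-Weighted MRI Using the Watershed Transform
    from Markers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Atlas-free brain extraction (skull stripping) for 3D
    T1-weighted head MRI.  A two-stage pipeline places a brain marker and a
    background marker using aggressive mathematical morphology with large,
    millimetre-sized structuring elements, then floods an inverted-T1 and a
    gradient-derived control surface with a marker-based watershed
    transform.  Parameterisations for human and macaque anatomy are
    provided, together with a synthetic head-phantom generator with
    voxel-exact ground truth, overlap metrics (Dice, Jaccard, sensitivity,
    specificity), NIfTI input/output and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
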