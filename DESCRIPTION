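Package: resectr
Title: Simulation of Brain Resection Cavities on Preoperative MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Generates simulated postoperative brain MRI from preoperative
    T1-weighted volumes and their parcellations, for self-supervised training
    of resection-cavity segmentation models. A geodesic sphere is perturbed
    with fractal simplex noise, rotated and scaled to a target volume,
    centred on a random cortical gray-matter voxel, voxelized, restricted to
    the resectable hemisphere, and filled with ventricle-matched
    cerebrospinal-fluid texture through a blurred alpha channel, yielding the
    simulated image together with its ground-truth cavity label. Includes
    NIfTI input/output with windowed-sinc resampling onto a canonical
    MNI-style grid, a synthetic head phantom for dependency-free testing, a
    declarative reconstruction of the compact 3D U-Net used downstream
    (closed-form parameter and receptive-field computation), and the
    evaluation statistics (Dice score, largest-component postprocessing,
    one-tailed Mann-Whitney U, Bonferroni-style correction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
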