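Package: srstcp
Title: Radiobiological Evaluation of Stereotactic Radiosurgery Plans for
    Infiltrative Brain Tumours
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Voxel-based tumour control probability (TCP) evaluation of
    stereotactic radiosurgery dose distributions for infiltrative brain
    tumours. Implements the Poisson TCP model with linear-quadratic cell
    survival on 3D dose grids, explicit models of clonogenic-cell
    infiltration beyond the delineated target (none, continuous exponential
    decay with distance, and stochastic per-voxel occupancy, truncated at a
    maximum infiltration distance), dose-to-structure-grid resampling, exact
    anisotropic Euclidean distance maps, the coverage-type conformity index,
    and a synthetic Gamma-Knife-like plan generator so the whole framework
    runs without patient data. Reads and writes NRRD rasters and reads NIfTI.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
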