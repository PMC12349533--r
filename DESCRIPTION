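Package: DualPoseReg
Title: Dual-Pose 2D/3D Rigid Registration of CT Volumes to Biplanar Radiographs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Rigid 2D/3D registration of a CT volume to paired frontal and
    lateral radiographs. Digitally reconstructed radiographs (DRRs) are
    rendered by perspective ray casting with trilinear interpolation, scored
    against the reference radiographs with a banded contour-point similarity
    built on Canny edge maps, and the six-degree-of-freedom pose is recovered
    with a phased differential-evolution optimizer (DE/rand/2 with
    stage-switched control parameters). Includes the standard benchmark
    functions used to characterize the optimizer, a procedural bone phantom
    generator for fully synthetic end-to-end testing, and readers/writers for
    MetaImage, NIfTI and PNG/TIFF data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    png,
    tiff,
    RNifti
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
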