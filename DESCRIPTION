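Package: hoquant
Title: Quantitative CT and Voxel Dosimetry for Holmium-166 Microspheres
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying holmium-166 microspheres on computed
    tomography and estimating voxel-level absorbed dose. Implements linear
    HU-versus-concentration calibration with saturation exclusion and a
    forced-through-zero rule, subtraction and thresholding quantification of
    post-injection CT volumes with conversion to concentration and
    radioactivity maps, dose-point-kernel generation for 166Ho by a
    condensed-history Monte Carlo transport, dose-rate convolution and
    cumulative absorbed-dose maps with dose-volume histograms, and synthetic
    CT phantom generators with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
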