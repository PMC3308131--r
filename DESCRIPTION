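Package: aerolung
Title: Aerated-Lung Volumetry by Seeded Region Growing for Murine Micro-CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Quantification of multifocal lung tumour burden in longitudinal
    murine micro-CT by seeded region growing of the aerated lung, using the
    segmented aerated volume as an inverse surrogate for tumour load.
    Provides Hounsfield-calibrated synthetic thorax phantoms with exact
    ground truth, 3D region growing with a percent-of-range intensity
    tolerance and triplicate averaging, overspill (leakage) diagnostics with
    seed repositioning, voxel-to-millilitre volumetry, repeated-measures
    mixed ANOVA and linear growth-kinetics fitting for longitudinal cohorts,
    and cumulative radiation-dose bookkeeping for repetitive scanning
    protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
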