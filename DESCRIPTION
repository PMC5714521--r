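Package: nmireg
Title: Whole-Body Multimodal Deformable Image Registration and Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage whole-body registration of paired 3D volumes from
    different modalities (MR to CT): a six-parameter rigid pre-alignment
    followed by a cubic B-spline free-form deformation, both driven by
    normalized mutual information estimated from random spatial samples and
    optimized by multiresolution steepest descent with a decaying gain
    sequence. Includes a complete registration-evaluation framework
    (landmark error, volume overlap, overlay error, and distance-map
    surface measures), cohort box-whisker statistics, and a seeded
    generator of paired pseudo-CT/pseudo-MR phantoms with known
    ground-truth deformations for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
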