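Package: gliomech
Title: Mechanically Coupled Reaction-Diffusion Modelling of Glioma Growth
    and the Predictability of MRI-Informed Calibration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates coupled tumor-cell and vasculature growth in a
    three-dimensional brain domain with a mechanically coupled
    reaction-diffusion model (stress-modulated diffusion, vasculature-
    dependent carrying capacity, distance-gated angiogenesis and vessel
    regression), degrades the simulated fields to chosen signal-to-noise,
    spatial-resolution and temporal-resolution levels, recalibrates the
    four global model parameters from the degraded time courses by
    Levenberg-Marquardt least squares, predicts forward, and quantifies
    parameter-recovery error and prediction accuracy (Dice overlap and
    Lin's concordance correlation) across the full experiment grid.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    minpack.lm,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
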