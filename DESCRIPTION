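Package: infantdot
Title: Diffuse Optical Tomography Analysis of Infant Emotional-Speech Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for high-density diffuse optical
    tomography (HD-DOT) studies of hemodynamic responses to blocked emotional
    speech in infants. Provides a layered optical head phantom with a
    diffusion-approximation sensitivity matrix, canonical-HRF response
    simulation with within-block habituation, a synthetic channel-data
    generator with physiology, drift and movement artifacts, signal
    preprocessing (resampling, zero-phase bandpass, superficial signal
    regression, artifact rejection, trigger exclusion), FIR deconvolution of
    condition-wise responses, Laplacian-regularized linear reconstruction of
    total-hemoglobin images, and group statistics: global field-of-view tests,
    adaptive voxel-based clustering with Bonferroni correction, and
    region-of-interest analysis with Tukey-Kramer post hoc tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    signal,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    withr,
    yaml,
    jsonlite,
    RNifti,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
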