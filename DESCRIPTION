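Package: sctgan
Title: Synthetic CT Generation from Cone-Beam CT by Supervised and
    Cycle-Consistent Adversarial Image Translation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for translating cone-beam computed tomography (CBCT)
    slices into synthetic CT with calibrated Hounsfield units. Provides a
    seeded pelvic phantom simulator with a parametric CBCT degradation model
    (cupping, beam hardening, gain/offset miscalibration, noise, field-of-view
    truncation, anatomical mismatch), the standard masking/clipping/resampling
    pre-processing pipeline, an Inception-augmented U-Net generator and a
    PatchGAN discriminator implemented on a compact CPU convolution engine,
    supervised (pixel-wise L1) and unsupervised (cycle-consistent adversarial)
    training routines with ADAM, and Hounsfield-accuracy evaluation
    (SSIM/PSNR/MAE) with patient-wise cross-validation and non-parametric
    model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    RNifti,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
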