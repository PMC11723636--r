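Package: mricascade
Title: Cascaded Dual-Domain Reconstruction of Undersampled Multi-Coil Cardiac MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstruction of accelerated 2-D multi-coil cardiac MR images by
    cascaded k-space-domain and image-domain convolutional networks interleaved
    with a multi-coil data-consistency (MCDC) projection. Provides variable-density
    Cartesian undersampling masks, centered orthonormal Fourier transforms,
    Biot-Savart simulation of receiver-coil sensitivity maps, Walsh adaptive coil
    combination and sensitivity estimation, compressed-sensing (wavelet ISTA) and
    single-domain U-Net baselines, SSIM/PSNR/RMSE evaluation, and a synthetic
    cardiac phantom generator so the full pipeline runs end-to-end without any
    external dataset. The small U-Net and its training loop (RMSProp, reduce-on-
    plateau learning rate, early stopping) are implemented natively with compiled
    convolution kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    rhdf5,
    jsonlite,
    withr,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    png
Config/testthat/edition: 3
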