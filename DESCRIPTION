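Package: flowct
Title: MAP Reconstruction of CT Volumes from Ultra-Sparse Projections with a
    3D Normalizing-Flow Prior
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs a three-dimensional chest CT volume from one or two
    noisy two-dimensional projection images by maximum-a-posteriori (MAP)
    optimization in the latent space of a 3D multi-scale normalizing flow
    (a GLOW-style invertible network with exact log-likelihood). Includes the
    flow itself, progressive bit-depth training, a depth-averaging projection
    operator with a Gaussian noise model for ultra-low-dose protocols,
    synthetic chest phantom generation, and 3D image-agreement metrics
    (SSIM, PSNR, MAE, NRMSE).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    ggplot2,
    generics,
    jsonlite,
    RNifti,
    png,
    tiff,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
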