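Package: lrdenoise
Title: Low-Rank Plus Sparse Matrix Decomposition for Grayscale Image Denoising
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Denoises 2-D grayscale images (MRI slices in particular) by
    decomposing the observed intensity matrix into a low-rank component and a
    sparse component via nuclear-norm / l1 convex relaxation (robust PCA),
    solved with an inexact augmented Lagrange multiplier scheme. Also provides
    a truncated-PCA path for low, dense noise, a non-local-means baseline
    denoiser for comparison, MSE/PSNR image-quality metrics, a seeded
    synthetic phantom generator with exact ground truth, PNG/NIfTI readers and
    writers, and a command-line interface tying the pipeline together.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
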