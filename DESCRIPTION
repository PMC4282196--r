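Package: dkimaps
Title: Diffusional Kurtosis Imaging: Phantom Simulation, Tensor Fitting
    and Voxel-Based Group Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for diffusional kurtosis imaging (DKI) of gray matter:
    simulation of multi-shell diffusion-weighted phantoms with Rician noise
    from known diffusion and kurtosis tensors, per-voxel weighted
    linear-least-squares estimation of the 22-parameter DKI signal model,
    derivation of mean (MK), axial and radial kurtosis maps via the
    diffusion-tensor eigenframe, Gaussian smoothing and gray-matter
    masking, voxelwise two-sample comparison with Monte-Carlo
    cluster-extent correction, region-of-interest correlation with
    addiction-severity scores, and demographic/clinical group tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    stats,
    utils,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), knitr, rmarkdown, jsonlite
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
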