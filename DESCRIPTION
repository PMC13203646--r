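Package: petldm
Title: Conditional 3D Latent Diffusion for CT-to-PET Synthesis with SUV-Space Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Two-stage conditional latent diffusion modelling for translating 3D CT volumes
    (Hounsfield units) into PET volumes (standardized uptake value, SUV), together with the
    full evaluation suite used for cross-modality PET synthesis: anatomy-guided preprocessing
    (RAS reorientation, resampling, intensity clipping, lung-base-to-head cropping), a
    KL-regularized 3D variational autoencoder, a denoising diffusion probabilistic model in
    latent space with CT conditioning via channel concatenation, masked SUV-space image
    metrics (MAE, PSNR, 3D SSIM), lesion-level detection and quantification metrics, and
    cohort statistics (t-based confidence intervals, exact paired Wilcoxon signed-rank
    tests). Includes a seeded generator of paired CT/PET phantoms with lesion masks so the
    whole pipeline is testable at desk scale without any imaging download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
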