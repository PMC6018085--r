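Package: pnlica
Title: Post-Nonlinear Group ICA and Functional Connectivity Analysis for
    Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reusable pipeline for two-group resting-state fMRI analysis:
    synthetic BOLD data generation with a post-nonlinear mixing model and
    planted group differences in functional connectivity, preprocessing
    (volume discard, motion-based exclusion, Gaussian smoothing, detrending,
    band-pass filtering), MDL model-order selection, post-nonlinear group ICA
    with dual-regression back-reconstruction, resting-state-network template
    matching by spatial correlation, voxel-wise functional-connectivity group
    comparison with Fisher z-transformed correlations, and Monte-Carlo
    cluster-extent multiple-comparison correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    signal,
    stats,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
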