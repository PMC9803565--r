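Package: btseg
Title: Brain-Tumour MRI Segmentation with Hybrid GCPSO-FCM Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An image-analysis pipeline for locating bright tumour-like lesions
    in 2-D grayscale MRI slices. Preprocessing couples an adaptive bilateral
    filter, whose spatial and range scales respond to local block-boundary
    discontinuities and texture activity, with a multiresolution wavelet
    framework (CDF 9/7 lifting transform and universal-threshold shrinkage of
    detail bands). Segmentation is fuzzy c-means clustering hybridised with
    guaranteed-convergence particle swarm optimisation (GCPSO), in which the
    global-best particle samples an adaptively sized box around the incumbent
    optimum. Downstream stages compute gray-level co-occurrence (GLCM) texture
    features at four orientations and two quantisation depths, train a
    maximum-margin classifier under five kernel families (linear, polynomial,
    Gaussian RBF, exponential RBF, ANOVA), and score results with MSE/PSNR and
    pixelwise confusion rates. A deterministic phantom generator provides
    brain-like test images with exact ground-truth masks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    png,
    tiff,
    jsonlite,
    kernlab,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse
Config/testthat/edition: 3
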