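Package: bwtseg
Title: Brain MR Tumor Segmentation with the Berkeley Wavelet Transform
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting and delineating tumors in
    2D brain magnetic-resonance slices: adaptive sigmoid contrast
    enhancement, threshold-based skull stripping, denoising with the triadic
    Berkeley wavelet transform (an orthonormal basis of piecewise-constant
    3x3 patches), threshold-and-morphology tumor extraction, intensity
    clustering of white matter, gray matter and cerebrospinal fluid,
    first-order and gray-level co-occurrence (Haralick) texture features,
    and a Gaussian-kernel support vector machine separating normal from
    abnormal slices. Includes image-quality (MSE, PSNR, SSIM, Dice) and
    confusion-matrix metrics, readers for PNG, TIFF, NIfTI and single-frame
    DICOM slices, and a synthetic brain phantom generator with exact
    ground-truth masks so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    EBImage,
    stats,
    utils,
    png,
    tiff,
    RNifti,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
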