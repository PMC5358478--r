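# bwtseg — brain-MR tumor segmentation with the Berkeley wavelet transform

`bwtseg` is an R implementation of a classical automated pipeline for
detecting and delineating tumors in 2D brain magnetic-resonance slices,
aimed at image-analysis researchers and method developers who need a
fully inspectable, fully tested reference chain rather than a clinical
tool. The stages are:

1. **Contrast enhancement** — a monotone sigmoid intensity remapping
   `u ↦ 1 / (1 + exp(gain · (cutoff − u)))` on normalized intensities,
   rescaled back to [0, 255].
2. **Skull stripping** — threshold + morphology: the bright skull
   annulus is detected as a ring-shaped connected component and the
   brain is its filled interior.
3. **Berkeley wavelet transform (BWT)** — a complete orthonormal 2D
   basis of nine piecewise-constant 3 × 3 patches (8 oriented zero-mean
   wavelets + 1 constant), applied with triadic (factor-3) scaling:
   critically sampled, Parseval-exact, perfectly invertible. Used here
   as a coefficient-shrinkage denoiser ahead of segmentation.
4. **Segmentation** — strict thresholding at the global cut-off 128
   inside the brain mask, one erosion, selection of the component
   maximizing *area × mean intensity*, dilation back; the remaining
   brain intensities are k-means-clustered (k = 3, fixed percentile
   initialization) into CSF / gray matter / white matter. Tumor area is
   reported in pixels, as a ratio of the raster, and in cm² when pixel
   spacing is known.
5. **Texture features** — 12 named statistics per region: mean, SD,
   histogram entropy and energy, skewness, kurtosis, plus the Haralick
   co-occurrence features (contrast, homogeneity, angular second
   moment, correlation, directional moment) averaged over the four
   distance-1 offsets, and a coarseness index.
6. **Classification** — a Gaussian-kernel (RBF) soft-margin SVM,
   `k(u, v) = exp(−γ‖u − v‖²)`, on standardized feature vectors,
   labelling slices *normal* vs *abnormal*.
7. **Evaluation** — MSE, PSNR (standard and literal conventions), SSIM,
   Dice overlap `2|A∩B|/(|A|+|B|)`, and confusion-matrix
   accuracy/sensitivity/specificity.

A synthetic head phantom (elliptical skull ring, concentric
CSF/GM/WM zones, optional hyperintense tumor, seeded Gaussian noise)
provides exact ground-truth masks, so every stage — and the end-to-end
classifier — is testable without MR data. Readers are included for
PNG, TIFF, NIfTI and single-frame DICOM slices; all inputs are
normalized to 8-bit grayscale rasters.

## Worked example

```r
library(bwtseg)

spec <- phantom_spec(shape = c(81, 81), noise_sigma = 5, seed = 7,
                     tumor = list(center = c(30, 48), radii = c(9, 7),
                                  intensity = 200))
ph <- make_phantom(spec)
ph
#> <phantom_truth> abnormal slice 81 x 81, tumor 197 px

st <- strip_skull(enhance_contrast(ph$image))
st$mask
#> <binary_mask> 81 x 81, 3489 foreground px (53.2%)

seg <- segment_tissues(bwt_denoise(st$image), st$mask)
seg
#> <segmentation_result> tumor 194 px (ratio 0.0296); wm/gm/csf 1391/1532/372 px
dice(seg$tumor_mask, ph$tumor_mask)
#> [1] 0.9872123
```

The phantom's tumor occupies 197 pixels; after enhancement, stripping
and denoising, the threshold + morphology extraction recovers 194 of
them with a Dice overlap of 0.987 against the exact ground truth, and
the three tissue masks partition the remaining brain. A 60-slice seeded
cohort run end-to-end through the classifier:

```r
ds <- make_dataset(20, 40, phantom_spec(), seed = 42)
res <- evaluate_pipeline(ds, seed = 7)
res$confusion
#> <confusion_matrix> TP 13  FN 0  |  FP 0  TN 7
res$metrics
#>    accuracy sensitivity specificity
#>         100         100         100
```

All 20 held-out slices (13 abnormal, 7 normal) are classified
correctly: the phantom's hyperintense tumors shift the brain-region
texture features enough for the RBF-SVM to separate the classes
perfectly under the committed noise level.

A thin command-line front end over the same functions lives at
`inst/cli/bwtseg.R`:

```sh
Rscript inst/cli/bwtseg.R phantom --seed 3 --tumor --out ph/
Rscript inst/cli/bwtseg.R segment --in ph/image.png --out seg/
Rscript inst/cli/bwtseg.R bench --seed 5 --out bench.json
```

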