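---
title: "Segmenting and classifying brain-MR tumors with bwtseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting and classifying brain-MR tumors with bwtseg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bwtseg)
```

## The problem

Delineating tumor tissue in a 2D brain magnetic-resonance slice, and
deciding whether a slice is normal or abnormal, is routinely done by
eye. `bwtseg` implements a classical automated pipeline for this task:
contrast enhancement, skull stripping, wavelet denoising, threshold +
morphology segmentation of the tumor and of the three normal tissue
classes (white matter, gray matter, cerebrospinal fluid), texture
feature extraction, and a Gaussian-kernel support vector machine that
labels slices. Every stage is an exported function; a synthetic head
phantom with exact ground truth makes the whole chain testable without
patient data.

Throughout, a slice is a `gray_image`: an integer raster in [0, 255].
Every reader min–max rescales to that range, which is what gives the
pipeline's single global threshold of 128 a consistent meaning across
8-bit PNGs, 12-bit DICOMs and float NIfTI volumes.

## Contrast enhancement

`enhance_contrast()` maps normalized intensities `u = I/255` through a
logistic curve `1 / (1 + exp(gain * (cutoff - u)))` and rescales the
result back to [0, 255]. The mapping is monotone, so it reorders
nothing; it only steepens contrast around `cutoff`. Defaults are
`gain = 10` and `cutoff = 0.5` — mid-scale, i.e. centered on the global
threshold — and in the large-gain limit the curve degenerates into that
very threshold. The enhancement is applied globally; a per-region
("adaptive") variant would change results only in slices with strong
intensity inhomogeneity, which the pipeline does not model. The
transform is deliberately *not* idempotent: applying it twice steepens
the curve further. A constant slice is mapped to mid-gray 128, the
fixed point of the rescaling convention.

## Skull stripping

The skull reads as a bright closed annulus around darker parenchyma.
`strip_skull()` binarizes at the threshold and then distinguishes two
regimes:

* **An annular bright component exists** (its hole-filled hull is at
  least twice its own pixel count). The brain is the ring's filled
  interior with the ring removed, reduced to its largest 8-connected
  component and hole-filled. The hull-to-area factor 2 is far from both
  extremes — a genuine skull annulus has a hull many times its area,
  a solid blob close to 1 — so the classification is insensitive to its
  exact value.
* **No annulus** (already-stripped or skull-free slices): the filled
  bright region is eroded once with the 3 × 3 box element to cut thin
  bridges, reduced to its largest component, dilated back and
  hole-filled.

A one-shot erosion cannot remove a multi-pixel skull ring, which is why
ring detection, not repeated erosion, does the separating. The output
mask is always a single 8-connected component, and the returned image
is exactly the input inside the mask and 0 outside. Re-stripping the
output (with a threshold below the tissue intensities) reproduces the
mask up to a one-pixel boundary band — the erosion/dilation pair is not
exactly the identity along high-curvature stretches of the boundary.

Connectivity is 8-connected everywhere and all structuring elements are
squares, the smallest symmetric choices. Ties between equally large
components go to the one whose first pixel comes earliest in raster
order, so results are deterministic.

## The triadic Berkeley wavelet transform

The transform's basis lives on 3 × 3 patches: eight zero-mean
piecewise-constant wavelets — horizontal, vertical and two diagonal
orientations, each in an even (symmetric) and odd (antisymmetric)
phase — plus a constant patch of value 1/3 per cell that carries the
local mean. `bwt_basis()` builds them from the 1D triadic vectors
`c = (1,1,1)/sqrt(3)`, `o = (-1,0,1)/sqrt(2)`, `e = (1,-2,1)/sqrt(6)`:
the axis-aligned wavelets are outer products with `c`, the diagonal
pairs are `o⊗o`, `e⊗e` and the symmetric/antisymmetric combinations of
`o⊗e` and `e⊗o`. Orthonormality is then inherited from the 1D vectors
rather than imposed numerically, and the fixed construction order is
locked by a golden-value test. Any orthonormal completion with this
orientation/phase structure would serve equally; this one is chosen for
being closed-form.

`bwt_forward()` tiles the raster into non-overlapping 3 × 3 blocks,
projects each block onto the nine patches, and recurses on the
DC/scaling plane for `levels` scales (default 2 — on 8-bit slices a
third scale adds coefficients whose blocks span 27 pixels, coarser than
any structure the segmentation uses). The transform is critically
sampled (coefficient count equals pixel count), satisfies Parseval's
identity exactly, and `bwt_inverse()` reconstructs to floating-point
round-off. Sides not divisible by `3^levels` are reflect-padded on the
bottom/right; the original shape is recorded and the padding removed on
inversion, so clinical sizes such as 274 × 278 pass through unchanged.

`bwt_denoise()` keeps the largest-magnitude fraction of wavelet
coefficients (DC always kept) and inverts. The default
`keep_fraction = 0.2` comes from an energy-compaction argument on
head-sized slices: tissue boundaries concentrate in roughly the top
fifth of coefficients, and cutting much deeper starts erasing real
edges faster than noise. The denoiser feeds the segmentation as a
preprocessing step and can be bypassed (`use_bwt = FALSE`,
`--skip-bwt`); the masks themselves are always produced by the
threshold + morphology stage, the smallest defensible role for the
transform in the segmentation.

## Tumor and tissue segmentation

`binarize()` is strict: a pixel exactly at the threshold is background.
`extract_tumor()` binarizes within the brain mask, erodes once (radius
`se_radius`, default 1) to remove thin bright structures, picks the
component maximizing *pixel count × mean intensity* — preferring large,
bright lesions — and dilates back. The score's tie-break is again
first-pixel raster order. An empty result is a warning, not an error:
it is the expected outcome on a normal slice.

`segment_tissues()` first extracts the tumor, then k-means-clusters the
remaining brain intensities with k = 3, initialized deterministically
at the 10th/50th/90th intensity percentiles; clusters are relabeled by
center as CSF < GM < WM. Excluding tumor pixels *before* clustering
matters: a slice with three tissue bands plus a bright tumor has four
intensity modes, and k = 3 would otherwise merge two tissue bands. With
the tumor removed, a noiseless three-band slice is recovered exactly.
The result also reports tumor area in pixels, the tumor-to-raster area
ratio, and — when pixel spacing is known from a DICOM/NIfTI header —
the area in cm² (`px · row_mm · col_mm / 100`).

## Texture features

`extract_features()` assembles the classifier's 12-name vector:

* Six first-order statistics over the region's pixels: mean and
  population standard deviation; skewness and kurtosis as third/fourth
  standardized moments (reported as 0, with a `degenerate` attribute,
  when the region is constant); entropy `-Σ p log2 p` and energy
  `Σ p²` on the normalized 256-bin histogram. Putting entropy and
  energy on the histogram — rather than on raw intensities, where a
  logarithm of a pixel value has no meaning — keeps both inside their
  conventional [0, 8]-bit and (0, 1] ranges.
* Five co-occurrence (Haralick) features — contrast, homogeneity
  (inverse difference moment), angular second moment, correlation, and
  the directional moment `Σ p |x − y|` — averaged over the four
  distance-1 offsets (0°, 45°, 90°, 135°). Intensities are quantized to
  `levels = 8` gray levels (standard radiomics practice; configurable),
  pairs are counted only when both pixels are in-region, and the matrix
  is accumulated symmetrically. The directional moment's `|x − y|`
  weighting is the only reading of that statistic that yields a
  nontrivial moment.
* Coarseness: the region's intensity sum scaled by `2^-(m+n)`. It is
  implemented exactly in this printed form; note the scale factor
  vanishes for realistically sized rasters, so the index only
  discriminates on small patches. It is carried for completeness of the
  vector, not because it drives the classifier.

## Quality and classification metrics

`mse()`, `ssim()` (Wang et al. form, uniform 8 × 8 sliding windows,
`c1 = (0.01·255)²`, `c2 = (0.03·255)²`) and `dice()` are conventional.
`psnr()` has two modes: the standard `10 log10(peak²/MSE)` (default)
and a `"literal"` mode `20 log10(peak/MSE)` — with the MSE rather than
its square root in the denominator — a form that circulates in parts of
the tumor-segmentation literature; the two differ by exactly
`10 log10(MSE)` dB, which the test suite asserts as an identity.

`classification_metrics()` reports accuracy, sensitivity and
specificity as percentages *truncated* at two decimals. Truncation, not
rounding, is the print convention of the clinical comparison tables the
package mirrors (e.g. 194/201 = 96.517…% printed as 96.51), and
`digits = NULL` returns full precision for anyone who prefers it.

## The classifier

`train_svm()` standardizes each feature (constant features get unit
scale instead of an error), then fits a soft-margin SVM with the
Gaussian kernel `exp(-γ ||u - v||²)` via the libsvm solver. The solver
is bought, not built: the contract is the decision function, and a
hand-rolled QP would add nothing but risk. Defaults are
`γ = 1/n_features` on the standardized scale (the common heuristic
`1/(n_features · variance)` with unit variance) and `cost = 1`; both
are arguments and CLI flags. Prediction matches features to the
training schema *by name*, and the decision value's sign is re-oriented
to the model's fixed first class so that it is a stable score —
libsvm's raw sign depends on which label it happens to meet first in
the training data.

`evaluate_pipeline()` chains everything per slice (enhance → strip →
denoise → features), makes a stratified seeded train/test split
(`train_fraction = 2/3`), and aggregates a confusion matrix with
*abnormal as positive*.

## The phantom: what it does and does not emulate

`phantom_spec()` / `make_phantom()` draw an elliptical head with a
bright skull annulus, concentric tissue zones (GM cortex ring, WM
interior, CSF ventricle core), an optional hyperintense elliptical
tumor, and additive Gaussian noise clipped to [0, 255]. The committed
defaults are CSF 30 / GM 80 / WM 120 / skull 220, tumor 200, noise
σ = 5, shape 81 × 81 (three triadic scales): all normal tissue below
the 128 threshold, skull and tumor above it — the contrast relations of
a T2/FLAIR-like slice. `make_dataset()` adds per-slice jitter of tissue
levels and tumor geometry from one seeded generator, with tumors placed
in the white-matter band, and mirrors a 2:1 abnormal:normal prevalence
in the benchmark cohort (20 normal / 40 abnormal).

What the phantom deliberately is *not*: anatomically realistic
geometry, Rician noise (clipped Gaussian is close at these SNRs and
keeps the generator trivial to reason about), partial-volume mixing,
bias fields, or heterogeneous tumor texture — phantom tumors are a
uniform bright level plus noise. Consequently, passing tests establish
that every formula is computed correctly, that the transform is exactly
orthonormal, that segmentation recovers exact ground truth when the
intensity model holds, and that the feature/classifier chain separates
the classes the phantom defines. They do **not** establish clinical
accuracy on real MR data, where intensity overlap between tumor and
normal tissue is the dominant difficulty.

## Numerical choices and degenerate inputs

* Global threshold 128 everywhere, always strict (`>`), always
  configurable.
* All component tie-breaks use first-pixel raster order; k-means uses
  fixed percentile initialization — no hidden randomness anywhere, and
  every stochastic step takes an explicit seed.
* Degenerate statistics (zero variance, degenerate GLCM marginals) are
  reported as 0 with a `degenerate` attribute rather than NaN.
* Empty masks: `dice()` on two empty masks errors (0/0); an empty tumor
  mask from `extract_tumor()` is a warning because it is a legitimate
  normal-slice outcome; an empty brain mask is always an error.
* Test problem sizes: 81 × 81 phantoms, 60-slice benchmark cohorts,
  ≤ 16 × 16 rasters for the brute-force oracle comparisons, 100 seeds
  for the property sweeps — sizes at which every oracle is exact and
  the whole suite runs in seconds.

## Limitations

Single 2D slices only (volumes are read slice-wise); no registration,
bias-field correction or atlas priors; the skull-stripping ring
detection assumes the annulus is closed at the binarization threshold;
`coarseness` as printed is scale-degenerate; and the benchmark numbers
quantify performance on the phantom's intensity model, not on patients.
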