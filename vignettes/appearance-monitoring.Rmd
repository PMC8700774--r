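---
title: "Multivariate appearance monitoring of fresh foods with visionqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multivariate appearance monitoring of fresh foods with visionqc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(visionqc)
```

## The monitoring problem

Preservation treatments for minimally processed vegetables (the package's
motivating system is high-pressure CO₂ pasteurization of ready-to-eat
carrot slices inside modified-atmosphere packages) must not make the
product *look* treated. Panel testing is slow and expensive; an
artificial-vision system can instead compare each treated or stored sample
against a statistical model of what fresh samples look like, and flag any
sample whose appearance could be distinguished from fresh with a stated
confidence.

`visionqc` implements that comparison as multivariate statistical process
control (MSPC) on image-derived appearance features. The null hypothesis
for each sample is "this sample's appearance conforms to the fresh
population"; rejection means the vision system can tell it apart from 95%
of fresh samples.

## Pipeline and model

### Standardization

Every scene contains a white reflectance reference and a black background.
For each channel, the affine map sending the measured white-reference mean
to 255 and the black-reference mean to 0 is applied pixel-wise, then the
result is clipped to `[0, 255]` and re-quantized (round half up). Two
reference points support exactly one affine correction per channel, which
is the minimal model that removes frame-wide gain and offset drift of the
illumination; nonlinear camera response is out of scope. Reference patches
are measured with central-80% trimmed means so isolated specular pixels
cannot bias them. When no layout is provided, the references are found
blindly: the frame is tiled into blocks (at most 1/16 of the frame side),
and the brightest and darkest connected runs of low-variance blocks are
refined to pixel resolution. An image without a separated bright uniform
patch and dark background raises a `reference_not_found` error.

### Segmentation

Pixels of the standardized image are clustered in RGB with k-means,
`k = 4` by default (background, sample, white reference, indicator).
Seeding is k-means++-style farthest-point selection from a caller-supplied
seed followed by Lloyd iterations, so segmentation is deterministic. The
sample cluster is the saturated, non-dark cluster whose mean hue is closest
to the configured sample hue (default 0.08 ≈ carrot orange; clusters with
saturation below 0.15 are never candidates, which rules out the white
reference, the gray indicator and the background).

The selected mask is cleaned by morphological opening (5 px disc brush),
closing with a frame-scaled brush (15% of the frame side), and convex-hull
filling. The hull step reflects a modelling assumption worth making
explicit: the sample is convex (a slice/disc), so strongly degraded tissue
— whitened patches that the clusterer assigns to the white cluster, even
at the rim — still belongs to the region of interest. Without it, heavy
whitening bites bays out of the mask and the inscribed rectangle collapses.
For non-convex samples set `convex_fill = FALSE`.

The largest axis-aligned rectangle inside the mask is found by the
histogram-stack dynamic program in `O(HW)`; ties are broken
deterministically toward the smallest `(top, left)`. Coordinates follow
R's 1-based inclusive convention throughout.

### Features (`M = 2576`)

* **Color, `M_C = 12`** — mean, population SD, moment skewness and Fisher
  excess kurtosis of each RGB channel over the ROI. Zero-variance input
  yields skewness = kurtosis = 0 by convention so degenerate crops stay
  finite and deterministic.
* **Wavelet texture, `M_W = 144`** — the ROI rectangle (trimmed to the
  largest centered sub-rectangle divisible by `2^levels`) is decomposed
  per channel with an orthonormal, periodized 2-D discrete wavelet
  transform; the four moment statistics are taken of every detail subband:
  4 stats × 3 subbands (H, V, D) × 4 levels × 3 channels = 144. The
  default family is the 8-tap Daubechies filter (four vanishing moments);
  Haar is available. This per-channel, four-level reading is the only
  simple factorization of 144 consistent with using the same four
  statistical indices as the color block, and it is a design decision of
  this package: published feature counts alone do not pin down the wavelet
  configuration. The transform is exactly invertible (`idwt2()`), which the
  tests use as an orthonormality oracle.
* **GLCM, `M_G = 2420`** — the grayscale rectangle (ITU-601 luma weights)
  is quantized to 11 equal-width gray levels and, for every displacement
  (distances 1–5 px × angles 0°/45°/90°/135°), the symmetric normalized
  co-occurrence matrix is computed; all 11² entries are kept per
  displacement: 121 × 5 × 4 = 2420. Keeping raw entries rather than
  Haralick summaries is again the only reading consistent with the feature
  count (no set of summary statistics divides 2420 this way). Quantization
  bins span the crop's own min–max range by default, matching the
  convention of the MATLAB tooling this pipeline emulates; a fixed range
  can be set via `glcm_gray_limits = c(0, 255)`.

Feature names encode family, channel/level/subband or
distance/angle/entry, and statistic; the order is fixed, and downstream
model projection matches by name, so column order never matters.

### The monitoring model

Fresh-sample feature vectors are autoscaled (mean-centered, unit sample
variance — the convention of latent-variable process-monitoring practice;
features span very different magnitudes, from intensities to
probabilities). Zero-variance columns (e.g. co-occurrence entries never
observed in calibration) are dropped and recorded. The top `A` right
singular vectors (default `A = 7`) give the loadings `P`; for a scaled
sample `z`, scores are `t = Pᵀz` and

* Hotelling's `T² = Σₐ tₐ²/λₐ` with `λₐ` the calibration score variances
  (distance from the fresh average within the model plane), and
* `Q = ‖z − P t‖²` (distance from the model plane).

The 95% limits are `T²_lim = A(O−1)/(O−A)·F_{A,O−A;0.95}` and the Box-type
`Q_lim = (ν/2μ)·χ²_{h;0.95}` with `h = 2μ²/ν`, where `μ` and `ν` are the
mean and **variance** of the calibration Q residuals. The variance reading
is deliberate: the weighted-chi-square form only matches its moments under
it, although such limits are often verbally described via a "standard
deviation"; `q_nu = "sd"` selects the other reading. Both limits use the
calibration form for all samples; the new-observation T² variant (an extra
factor `(O+1)/O`) sits behind `t2_limit(form = "new")` and is negligible at
`O = 336`. A sample conforms only if **both** statistics fall strictly
below their limits — a sample exactly at a limit is rejected.

Degenerate edge: if `A` equals the data rank the model reconstructs
calibration exactly, all calibration residuals are zero and `Q_lim`
degenerates to 0; `A` above the rank is an error.

## The synthetic scene generator

No public image set exists for this kind of study, so the generator is a
first-class, tested module that stands in for the camera fixture. A scene
is a near-black background (level 5), a near-white reference patch (level
250), a checkerboard dimensional indicator, and the sample disc. The disc
interior is a base color (default carrot orange `230/130/40`) plus a
Gaussian random field (smoothed white noise, correlation length 6 px, SD
10 intensity units — giving the texture features a controllable ground
truth) plus independent per-pixel noise (SD 8). Degradation is modeled as:

* **whitening** — randomly placed blotches blended fully toward the white
  reference level until they cover a target fraction of the disc area,
  emulating surface whitening of dehydrated, lignified tissue;
* **color drift** — an RGB shift of the base color;
* **texture change** — an increment of the texture-field amplitude.

The whole frame finally passes through an affine illumination model
(`gain·I + offset`) and 8-bit quantization. Between-sample variability
(fresh population) draws each slice's base color (SD 6 per channel) and
texture amplitude (SD 2), and each imaging event draws its own
illumination gain (SD 0.02), so standardization has real work to do.
Effects are keyed by (condition, storage day) and must be monotone
non-decreasing in storage day; severities that push a parameter outside
its bounds are clipped with a warning.

The default frame is 512×512 with geometry proportional to the real
fixture's scene; features are resolution-configurable, and the test suite
uses 96–128 px frames, where a full render–standardize–segment–extract
pass takes well under a second.

What the generator does **not** emulate: real carrot anatomy (rings, core),
specular highlights, shadows, through-film imaging, camera optics and
nonlinear response, and spatially varying illumination. Passing tests
therefore demonstrate that the pipeline recovers known ground truth under
controlled, idealized variability — not that the features are sufficient
for any particular real product.

## Study bookkeeping

The default `study_design()` reproduces the full experimental inventory of
the motivating study: 3 MAP compositions × (4 fractional-factorial + 3
replicated-center) treatment runs × 4 control times (0/3/7/14 days) × 2
replicates = 168 treated packages, plus one untreated control package per
MAP per non-zero control time (9). Every package holds 2 slices, each
imaged twice (fresh before packaging; after treatment/storage), giving
336 fresh, 336 treated and 36 control images — 708 in total. Control
packages' images all carry state `"control"` (including their day-0
acquisition), so the fresh calibration population consists exactly of the
336 fresh images from treated packages; the 2-slices × 2-events control
schedule is the only arithmetic consistent with 36 control images from 9
packages. Treatment conditions are validated against the apparatus
envelope (25–50 °C, 4–20 MPa).

## Numerical choices and problem sizes

* All randomness flows through explicit seeds; per-image streams are
  derived from the cohort seed and the record index, so cohorts are
  reproducible image-by-image and identical inventories are produced for
  different seeds.
* 8-bit quantization is round-half-up everywhere (`floor(x + 0.5)`).
* k-means uses Lloyd iterations from deterministic farthest-point seeds;
  on well-separated synthetic scenes the resulting mask is stable to the
  seed (IoU ≥ 0.99 in the tests).
* The DWT uses circular (periodized) boundary handling, which keeps the
  transform orthonormal on rectangle sides divisible by `2^levels`; the
  rectangle is center-trimmed to such a size rather than padded.
* Oracle tests pin the numerics: GLCMs against brute-force pair counting
  on random crops up to 16×16; the inscribed-rectangle DP against
  exhaustive search on random masks up to 32×32; T²/Q against a dense
  eigendecomposition on a 50×10 matrix; F quantiles against the
  beta-distribution relation.
* Monte-Carlo validation of the limits runs at the study's calibration
  size: a 20-variable Gaussian with rank-7 signal plus isotropic noise,
  `O = 336`, `A = 7`, averaged over independent calibration replicates.
  The end-to-end effect-recovery check calibrates on 336 fresh synthetic
  images (96 px frames) and scores 84 treated images per whitening
  severity level.

## Known limitations

* **Held-out Q coverage runs below nominal.** The Q limit is built from
  calibration residual moments, and the calibration residuals are
  optimistic: center, scales and loadings are estimated on the same data,
  so a held-out in-control sample's Q is inflated by roughly `(1 + p/O)`.
  At 20 variables and `O = 336` the measured held-out coverage is ~93–94%
  instead of 95% (the T² limit's F form already carries its finite-sample
  correction and holds ~95%). The effect grows as the feature count
  approaches the calibration size: with a handful of calibration images
  against 2576 features, held-out rejection of perfectly in-control
  samples is far above the nominal 5%, which is why absolute false-alarm
  claims are only meaningful at study-scale calibration (the suite
  measures ~6% at `O = 336`).
* Conformance is a per-image verdict; the package does not model package,
  slice or replicate as random effects.
* The number of components `A` is a configuration input, not selected by
  cross-validation.
* Feature extraction assumes one convex sample per scene.
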