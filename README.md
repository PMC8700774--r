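# visionqc

Artificial-vision appearance quality monitoring for fresh foods.

Minimally processed foods (the motivating case is ready-to-eat carrot slices
preserved by high-pressure CO₂ treatment inside modified-atmosphere
packages) can degrade visibly long before they spoil microbiologically:
surfaces whiten from dehydration and lignification, colors drift, texture
changes. `visionqc` implements an imaging pipeline that decides, with a
stated statistical confidence, whether a treated or stored sample still
*looks fresh*:

1. **Scene simulation** — synthetic imaging scenes (sample disc, white
   reflectance reference, black background, dimensional indicator) with
   controllable degradation, plus the fractional-factorial study-design
   bookkeeping (`enumerate_design()`: 168 treated packages, 9 control
   packages, 708 images under the default design).
2. **Standardization** — per-channel two-point color correction against the
   in-scene white and black references, so frame-to-frame lighting drift
   cancels out.
3. **Segmentation** — k-means color clustering extracts the sample region
   of interest; a histogram-stack dynamic program finds its largest
   inscribed rectangle.
4. **Features** — an `M = 2576` appearance descriptor per image:
   `M_C = 12` color moments (mean, SD, skewness, kurtosis per RGB channel),
   `M_W = 144` wavelet texture statistics (4 moments × 3 detail subbands ×
   4 levels × 3 channels, Daubechies-4), and `M_G = 2420` gray-level
   co-occurrence entries (11² levels × 5 distances × 4 angles).
5. **Monitoring** — a PCA model with `A` components is calibrated on fresh
   samples only. Each new sample is scored by Hotelling's

   `T² = Σₐ tₐ²/λₐ`  and the squared prediction error `Q = ‖z − P t‖²`,

   with 95% control limits

   `T²_lim = A(O−1)/(O−A) · F_{A,O−A;0.95}` and
   `Q_lim = (ν/2μ) · χ²_{2μ²/ν;0.95}`,

   where `O` is the calibration size and `μ`, `ν` are the mean and variance
   of the calibration Q residuals. A sample **conforms** to fresh
   appearance only if both statistics fall strictly below their limits.

The pipeline is tidyverse-native: inventories, feature tables, chart points
and rejection summaries are tibbles; fitted models have `tidy()`,
`glance()` and `autoplot()` methods; `plot_control_chart()` draws the
Q-versus-T² chart with dashed limits.

## Worked example

```r
library(visionqc)

# one synthetic scene, standardized and segmented
lay  <- scene_layout(128, 128)
img  <- render_scene(lay, appearance_params(seed = 1))
std  <- standardize_image(img, locate_references(img, layout_hint = lay))
mask <- segment_roi(std, seed = 1)
x    <- extract_features(std, mask)
length(x)
#> [1] 2576
round(x[c("col_R_mean", "col_G_mean", "col_B_mean", "col_R_sd")], 2)
#> col_R_mean col_G_mean col_B_mean   col_R_sd
#>     232.56     128.94      35.25      12.50
```

The ROI mean color sits at the simulated carrot orange (base `230/130/40`
plus texture), and the within-disc SD reflects the texture and noise
settings.

A miniature end-to-end study — one treatment condition whose whitening
worsens with storage, scored against a fresh-calibrated model:

```r
d  <- study_design(maps = "MAP1",
                   conditions = treatment_condition("TC2", 40, 6, 15),
                   center_replicates = 1, control_times = c(0, 7),
                   replicates = 4, controls = FALSE)
eff <- effect_model_linear("TC2", days = c(0, 7), whitening0 = 0.05,
                           whitening_per_day = 0.03)
st <- run_study(d, effects = eff, layout = lay, ncomp = 5, seed = 2026)
st$rejections
#> # A tibble: 2 × 7
#>   state   condition storage_day     n n_reject rejection rejection_pct
#>   <chr>   <chr>           <dbl> <int>    <int>     <dbl>         <dbl>
#> 1 treated TC2                 0     8        8         1           100
#> 2 treated TC2                 7     8        8         1           100
```

Every treated sample is flagged: 5% surface whitening is already far
outside the fresh population, and a 16-image calibration set makes the
limits tight for held-out samples (see the vignette for the calibration-size
discussion). `autoplot(st$model)` draws the calibration control chart;
`plot_control_chart(st$chart, st$model, color = "storage_day")` overlays
the scored samples.

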