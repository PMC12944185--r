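# kineticrad

Kinetic-curve parametric radiomics for dynamic contrast-enhanced MRI
(DCE-MRI), aimed at imaging scientists studying breast cancer molecular
subtypes (HR+/HER2−, HER2+, TNBC) and at methodologists who need a fully
testable, self-contained implementation of the parametric-radiomics
pipeline.

A registered DCE series (one pre-contrast volume plus N ≥ 3 post-contrast
volumes at times *t₁ < … < t_N* after injection) is converted, voxel by
voxel, into two kinetic parametric images. With normalized signal
*sᵢ = Iᵢ / I_pre*:

* **TIC-WIR** — wash-in rate, `(I_peak_norm − 1) / T_peak` (s⁻¹), where
  `I_peak_norm = max(s₁, s₂, s₃)` is the normalized peak within the first
  three post-contrast phases and `T_peak` its time;
* **TIC-Area** — the trapezoidal area under the normalized curve from
  injection (value 1 at *t = 0*) to *t_N*, divided by *t_N*.

Each parametric image (and the raw peak-enhancement phase, the "MR-ORI"
baseline) is resampled to 1 mm³, discretized with a fixed bin width, and
summarized by **851 standardized radiomics features** (14 shape + 18
first-order + 75 texture on the original image; first-order + texture on
each of 8 undecimated Coiflet-1 wavelet bands). A three-step selection
(variance ≥ 0.01 → |r| > 0.8 correlation pruning → multinomial LASSO,
10-fold CV) feeds one-vs-all gradient-boosted models with
square-root-balanced class weights; per-class probabilities are
isotonically calibrated and stacked into a decision-level **TIC-Combined**
fusion model. Evaluation: micro/macro/one-vs-rest AUC with 1000-replicate
bootstrap CIs, DeLong comparisons, precision/recall/F1, calibration curves,
and exact TreeSHAP attributions.

Because clinical DCE data cannot ship with the package, a synthetic phantom
module generates registered DCE cohorts whose voxel kinetics are known
analytically (piecewise-linear enhancement with spatially correlated
wash-in and washout fields), so every stage — maps, features, selection,
models, statistics — is validated against exact oracles.

## Worked example

```r
library(kineticrad)

# one synthetic patient: 32^3 grid, 5 post-contrast phases at 60..300 s
p <- generatePatient(phantomSpec(), "TNBC", seed = 42)
p$series
#> DCESeries 'phantom': 32x32x32 voxels, 5 post-contrast phases at
#> 60/120/180/240/300 s, spacing 1x1x1 mm

wir <- computeWIRMap(p$series)
wir
#> ParametricMap [WIR] 'phantom': 32x32x32 voxels, range 0..0.03114
mean(mapArray(wir)[maskArray(p$mask)])
#> [1] 0.02142708        # the generating class mean is 1.4/60 = 0.02333

f <- extractFeatures(mapArray(wir), maskArray(p$mask),
                     config = extractionConfig(binWidth = 0.001))
length(f)
#> [1] 851
f["original_shape_Elongation"]
#> original_shape_Elongation
#>                 0.9183    # ellipsoidal lesion, semi-axes randomized
```

The in-mask mean of the wash-in map recovers the class's generating wash-in
rate (up to the spatially correlated voxel-level spread), and the feature
vector is the full named 851-feature panel — e.g.
`wavelet-LLH_glszm_GrayLevelNonUniformityNormalized` quantifies how
unevenly gray levels are distributed in the low-low-high wavelet band.

The full pipeline on a 60-patient cohort (stratified 8:2 split):

```r
cfg <- runConfig(phantom = phantomSpec(nPerClass = c(26L, 21L, 13L), seed = 1),
                 seed = 1)
res <- runPipeline(cfg, runDir = "run1")
round(sapply(res$reports, function(r) r$microAUC["auc"]), 3)
#> TICWIR.auc TICArea.auc  MRORI.auc fusion.auc
#>      1.000       0.823      0.458      1.000
```

On phantoms whose classes differ only kinetically, the single-phase MR-ORI
baseline sits near chance while both parametric-map models discriminate
well — the core claim of the parametric-radiomics approach — and the fused
model tracks the best base model.

A thin command-line wrapper is installed at
`inst/cli/kineticrad.R` (`phantom`, `maps`, `run` subcommands).

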