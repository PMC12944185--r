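---
title: "Kinetic-curve parametric radiomics for DCE-MRI: methods and design notes"
author: "kineticrad authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic-curve parametric radiomics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the method

Dynamic contrast-enhanced MRI (DCE-MRI) acquires one pre-contrast and a
handful of post-contrast T1-weighted volumes after injection of a gadolinium
agent. Breast cancer molecular subtypes (HR+/HER2−, HER2+, TNBC) differ in
vascularity and perfusion, which shows up in the *time-intensity curve* (TIC)
of each voxel. Conventional TIC analysis averages the curve over a manually
drawn region and loses all spatial heterogeneity; conventional radiomics
analyzes a single phase image and loses the temporal dimension.

`kineticrad` implements the middle path: each voxel's TIC is condensed into
two semi-quantitative kinetic parameters, producing two *parametric images*
that preserve spatial resolution while encoding temporal behavior. Radiomics
then quantifies heterogeneity on those images.

With normalized signal \(s_i = I_i / I_{\mathrm{pre}}\) at post-contrast
time \(t_i\) (seconds after injection):

* **TIC-WIR** (wash-in rate, s⁻¹):
  \(\mathrm{WIR} = (I^{\mathrm{norm}}_{\mathrm{peak}} - 1) / T_{\mathrm{peak}}\),
  where \(I^{\mathrm{norm}}_{\mathrm{peak}} = \max(s_1, s_2, s_3)\) is the
  normalized peak within the *first three* post-contrast phases and
  \(T_{\mathrm{peak}}\) its time. Ties take the earliest phase.
* **TIC-Area** (dimensionless): the trapezoidal integral of the normalized
  curve through \((0, 1), (t_1, s_1), \dots, (t_N, s_N)\), divided by
  \(t_N\). A non-enhancing voxel has Area exactly 1.

Downstream, each parametric image (and, as a baseline, the raw
peak-enhancement phase image, "MR-ORI") is resampled to 1 mm³, discretized
with a fixed bin width, filtered into 8 undecimated wavelet bands, and
summarized by 851 standardized radiomics features. A three-step selection
(variance 0.01 → |r| > 0.8 correlation pruning → multinomial LASSO with
10-fold CV) feeds one-vs-all gradient-boosted models; their per-class
probabilities are isotonically calibrated and stacked into a decision-level
fusion model. Evaluation covers micro/macro/one-vs-rest AUC with
1000-replicate bootstrap CIs, DeLong comparisons, precision/recall/F1,
calibration curves, and exact TreeSHAP attributions.

# Numerical and design choices

Several points are underdetermined by the method description alone; the
package fixes them as follows.

**Degenerate voxels.** Voxels whose pre-contrast signal is at or below
\(10^{-6}\times\) the in-volume maximum cannot be normalized; both maps set
them to 0 and count them (`nDegenerate`), so no NaN/Inf ever reaches the
texture matrices.

**Baseline point of the area integral.** The integral starts at injection,
which requires a curve value at \(t = 0\); the normalized pre-contrast value
is 1 by construction. "Total acquisition time" is read as \(t_N\), making
Area dimensionless and comparable between 4- and 5-phase protocols.

**Non-enhancing voxels.** The wash-in rate is floored at 0: a voxel whose
normalized peak in the first three phases is below baseline carries no
wash-in information, and a negative rate would only encode noise.

**Resampling.** Images are interpolated with separable natural cubic
splines, masks with nearest-neighbour lookup; when the input grid already
matches the target the data pass through untouched. Interpolation reproduces
constants exactly.

**Discretization.** The min-anchored fixed-bin-width rule
\(\lfloor (v - \min v) / w \rfloor + 1\) is applied to in-mask values after
resampling. Its translation invariance makes all texture features invariant
to adding a constant to the image. The conventional bin width 5 suits raw MR
signal amplitudes (hundreds of units); the parametric maps live on entirely
different scales — WIR around 0.01 s⁻¹, Area around 1–3 — where a width of 5
would collapse the ROI to a single gray level. `runConfig()` therefore
carries per-source bin widths, defaulting to 0.001 (WIR), 0.05 (Area) and 5
(MR-ORI), chosen to give a few tens of gray levels in each source; this is
the package's resolution of a point the method leaves open.

**Wavelet filter bank.** A single-level undecimated separable 3D transform
with Coiflet-1 filters and half-sample symmetric padding produces the 8
same-shape bands `LLL…HHH` (letter = filter per array axis). Coiflet-1 is
the de-facto default of the standard radiomics toolchain; high-pass bands of
a constant image are exactly zero.

**Feature panel.** Per image: 14 shape (mask only, computed once), 18
first-order, 24 GLCM + 16 GLRLM + 16 GLSZM + 5 NGTDM + 14 GLDM texture
features on the original image, and first-order + texture on each wavelet
band: \(107 + 8 \times 93 = 851\). GLCM is symmetric, distance 1, averaged
over the 13 unique 3D directions; GLRLM likewise. Gray values in texture
formulas are the actual surviving level values (empty levels removed);
dependence counts include the center voxel. Zero-variance conventions
(skewness/kurtosis 0, GLCM correlation 1, NGTDM busyness 0 with one gray
level) keep the feature table NaN-free. Surface area is exposed-voxel-face
area and volume is voxel-count volume (no surface meshing); principal-axis
lengths, Elongation and Flatness come from the eigenvalues of the voxel
coordinate covariance.

**Selection order.** The 0.01 variance threshold is applied to *raw*
feature variances — applied after z-scoring it would remove nothing — and
z-scoring happens just before the LASSO, which needs comparable scales. The
correlation scan removes, from the most correlated remaining pair, the
member with the higher mean absolute correlation to everything else (ties:
the later column), iterating until no |r| exceeds 0.8; fixing the order
makes the step reproducible. The multiclass LASSO is multinomial with one
penalty, chosen at the CV deviance minimum; the kept set is the union of
nonzero supports across classes and is frozen before any validation data is
touched.

**Models.** The one-vs-all multiclass boosted model is realized as three
independent binary gradient-boosted tree models (xgboost,
`binary:logistic`), each sample weighted by the square-root-balanced weight
of its true class, \(w_c = \sqrt{\max_k n_k / n_c}\). Hyperparameters
default to depth 6, up to 500 rounds at learning rate 0.05, early stopping
on a 10% stratified internal holdout. Per-class probabilities are
renormalized to a distribution only where a distribution is needed;
calibrated probabilities entering the fusion model are deliberately *not*
renormalized (they are features, and renormalization would destroy the
marginal calibration the isotonic maps just learned). The fusion
meta-classifier is the same boosted-tree family on the fixed-order
6-column input.

**Calibration and stacking.** Isotonic (pool-adjacent-violators) regression
of the class indicator on training-set predictions, per class; prediction
linearly interpolates between the fitted knots (clamped to the knot range),
which keeps the map monotone while preserving ranking between knots. The
pipeline fits the calibrators — and trains the fusion model — on
*out-of-fold* training predictions: five stratified calibration folds, with
the entire per-source chain (three-step selection plus boosted model) refit
on each fold complement, so no training row's prediction has seen its own
label. This is the standard stacked-generalization discipline (and what
`CalibratedClassifierCV` does around a pipeline): calibrating on in-sample
predictions of a well-fitting model degenerates into a 0/1 step that feeds
the fusion stage nothing but thresholded labels, and lets selection-bias
noise compete with genuine signal inside the meta-model. The frozen
calibrators are applied unchanged to the final models' validation outputs.
`fitCalibrators()` also exposes plain CV-on-selected-features and pure
in-sample variants for study.

**Evaluation.** OvR AUC is the Mann–Whitney statistic with midrank ties;
micro-average AUC flattens (sample, class) pairs; macro averages the three
OvR AUCs. The DeLong comparison of micro-average AUCs treats the flattened
pairs as the paired units, mirroring how the micro AUC itself is defined —
the within-patient correlation between a patient's three flattened entries
is not modeled, a deliberate and documented simplification. Bootstrap CIs
are percentile, resampling *patients* (all of a patient's class
probabilities move together); resamples missing a class are skipped and more
than 10% skips is an error. The three pairwise DeLong tests are reported
without multiplicity correction, flagged as such. Attributions are exact
TreeSHAP values on the per-class margin (log-odds) scale, satisfying local
accuracy to numerical precision.

# The synthetic phantom: what it emulates, what it does not

No imaging data ships with the package; every stage is exercised on
synthetic DCE phantoms whose ground truth is known analytically. Each
patient is an ellipsoidal lesion (randomized semi-axes 4.5–7.5 voxels,
guaranteeing ≥ 200 voxels) in a 32³ grid at 1 mm³, with a smooth positive
pre-contrast background (baseline 100, 2% spatial variation). In-lesion
voxels follow a piecewise-linear normalized enhancement curve

\[ s(t) = 1 + w\,\min(t, t_p) + m\,\max(0, t - t_p), \]

with the voxel wash-in rate \(w\) and late slope \(m \le 0\) drawn from
spatially correlated Gaussian fields (Gaussian-filtered white noise,
correlation length 1.8 voxels). Sampling at 60/120/180/240/300 s (a 4-phase
preset exists) with \(t_p\) at a sampled phase makes both parametric maps
exactly computable from the generating fields — the oracle used by the map
tests — and additive Gaussian acquisition noise (sd 1 raw unit, i.e. ~1% of
baseline) is applied on top.

The three subtype classes are separated *kinetically*, not geometrically:
time-to-peak 180/120/60 s, wash-in mean \(1.4/t_p\) (so the peak enhancement
amplitude, ≈ 1.4 above baseline, is identical across classes), washout slope
−5·10⁻⁴/−1·10⁻³/−2·10⁻³ s⁻¹, and voxel-level wash-in spread 20% of the
class mean. Because amplitude and spatial correlation statistics match
across classes, a single post-contrast phase image is nearly uninformative,
while the parametric maps see three-fold differences in kinetic magnitude
and spread — the phantom realization of the claim that kinetic parametric
images add value over single-phase radiomics. The default cohort mixes
classes 15:12:7, a 1/20-scale version of a realistic 299:235:142 clinical
imbalance.

What the phantom does **not** emulate: pharmacokinetics (no arterial input
function or Tofts-type modeling), motion and registration error, scanner-
and protocol-dependent signal nonlinearity, rim enhancement or necrotic
cores, and non-ellipsoidal morphology. Passing end-to-end tests therefore
demonstrates that the pipeline's machinery is correct and that it recovers
known kinetic class structure; it says nothing about classification
performance on clinical data.

# Problem sizes used in the test battery

The shipped tests and the acceptance script run, on one CPU: a 60-patient
phantom cohort (26/21/13, 8:2 stratified split) for the end-to-end ordering
checks; a second 60-patient cohort whose classes share their wash-in
behavior and differ only in washout (so the Area signal dominates the WIR
signal by construction) for the fusion-attribution ordering; texture oracles
on ≤ 5×5×3 ROIs; 20-seed LASSO support-recovery simulations at n = 300; and
200 synthetic cohorts (n = 100, true AUC 0.8, 1000-replicate CIs) for
bootstrap coverage. These sizes were chosen as the smallest at which the
checked properties are stable.

# Known limitations

* Surface area/volume are voxel-based, not mesh-based; absolute values of
  Sphericity and SurfaceArea differ from mesh-based implementations (the
  PCA-based axis features do not).
* The micro-average DeLong test ignores within-patient correlation (see
  above); its p-values are approximate for the 3-class micro problem.
* When a cohort is genuinely separable even under cross-validation, the
  isotonic calibrators still collapse toward a 0/1 step and the fused
  model's validation scores tie on the resulting plateaus; at desk-scale
  cohorts (tens of patients) this can cost the fusion model a few AUC
  points relative to its best base model. The effect shrinks with cohort
  size.
* Feature-stability analysis (segmentation perturbations, rebinning) is not
  performed.

# A minimal run

```r
library(kineticrad)
cfg <- runConfig(phantom = phantomSpec(nPerClass = c(26L, 21L, 13L), seed = 1),
                 seed = 1)
res <- runPipeline(cfg, runDir = "run1")
sapply(res$reports, function(r) r$microAUC)
res$fusionAttribution$meanAbs
```
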