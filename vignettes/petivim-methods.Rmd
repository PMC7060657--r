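---
title: "PET-IVIM analysis: models, parameters and design choices"
author: "petivim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PET-IVIM analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petivim)
```

# The problem

Pelvic lymph-node staging drives treatment choice in cervical cancer, but
preoperative node assessment on PET (visually increased FDG uptake) and on
MRI (short-axis diameter) is imperfect — PET reading in particular is
specific but insensitive. A simultaneous PET/MR examination also yields
quantitative descriptors of the *primary tumor*: metabolic burden from PET
(SUVmax, SUVmean, MTV, TLG) and microstructural/perfusion parameters from
multi-b-value diffusion MRI via the intravoxel incoherent motion (IVIM)
model. `petivim` implements the full quantitative chain from voxel data to a
combined logistic prediction model for node metastasis, together with a
synthetic-data module that makes every stage testable without patient data.

# The IVIM signal model and its fitting

## Forward model

Diffusion-weighted signal in perfused tissue decays bi-exponentially with
the diffusion weighting $b$ (s/mm²):

$$\frac{S(b)}{S(0)} = f\,e^{-b\,(D^* + D)} + (1-f)\,e^{-b\,D},$$

with $D$ the pure (tissue water) diffusion coefficient, $D^*$ the
pseudo-diffusion coefficient of capillary blood and $f$ the perfusion
fraction. Note the fast compartment decays at rate $D^* + D$: the two
exponents are separated by exactly $D^*$. `ivim_signal()` evaluates this
model; it is strictly decreasing in $b$ and equals 1 at $b = 0$ for any
valid parameters.

The default acquisition schedule is the 14-value axial IVIM protocol
(`default_b_values()`): 0, 10, 25, 50, 75, 100, 125, 150, 200, 300, 400,
600, 800, 1000 s/mm² — eight values below 200 sampling the perfusion decay
and six at/above 200 sampling the tissue compartment.

## Segmented (two-step) fit

`fit_ivim_segmented()` uses the standard asymptotic decomposition:

1. **High-b log-linear fit.** For $b \ge b_{thr}$ the pseudo-diffusion term
   has decayed to numerical irrelevance, so $\log S$ is linear in $b$ with
   slope $-D$ and intercept $\log A$, $A = (1-f)\,S(0)$.
2. **Perfusion fraction from the intercept gap.**
   $f = (S(0) - A)/S(0)$.
3. **One-dimensional $D^*$ fit.** With $D$ and $f$ held fixed, $D^*$ is the
   bounded least-squares minimizer over the full curve
   (`stats::optimize`, interval $[3, 300]\times 10^{-3}$ mm²/s,
   tolerance $10^{-10}$).

The threshold defaults to $b_{thr} = 200$ s/mm², the natural split of the
schedule above; it is configurable. The split is an *approximation*: the
residual perfusion signal at $b \ge b_{thr}$ is
$\tfrac{f}{1-f} e^{-b_{thr} D^*}$ relative to the tissue term, about
$4\times10^{-5}$ at the typical $D^* = 42.6 \times 10^{-3}$ mm²/s but ~2%
at a slow $D^* = 15\times10^{-3}$ mm²/s. Noiseless round-trip recovery to
≤ 1% therefore holds over the pseudo-diffusion range actually observed in
cervical tumors ($D^* \approx 43 \pm 15 \times 10^{-3}$ mm²/s), which is
what the test suite asserts; fits with very slow $D^*$ inherit the
asymptotic bias of every segmented IVIM implementation.

Degenerate limits are explicit: computed $f$ is clamped to $[0,1]$ with the
clamp recorded, and when $f$ is numerically zero $D^*$ is unidentifiable
and returned as `NA` with a flag, never as an arbitrary number.

## Full (simultaneous) fit

`fit_ivim_full()` refines all four parameters $(S_0, D, D^*, f)$ jointly by
bounded nonlinear least squares (L-BFGS-B) initialized from the segmented
fit. Bounds — $D \in (0, 3]\times10^{-3}$, $D^* \in [3, 300]\times10^{-3}$
mm²/s, $f \in [0, 0.5]$ — keep the slow and fast compartments separated and
cover the observed parameter ranges with ample margin. If the joint
optimization fails or worsens the residual, the segmented result is
returned and flagged (`fallback = TRUE`), so the full fit never degrades
its initialization.

## ADC and perfusion contamination

`fit_adc()` fits the mono-exponential (single-index) model by weighted
log-linear least squares over *all* b-values. Because the low-b range is
perfusion-sensitive, ADC systematically exceeds the true $D$ whenever
$f > 0$ — the fitted single exponent absorbs "false diffusion" from
capillary flow. This inequality is asserted as a property test. A
conventional two-point ADC (first/last b-value) is available behind
`two_point = TRUE`. Log-domain steps use weights $\propto S^2$, the
delta-method variance correction that de-biases low-signal points.

## Maps and VOI statistics

`fit_maps()` applies the voxel fit independently inside a mask (no spatial
regularization), producing ADC/D/D*/f maps, per-voxel RMS residuals and a
convergence flag; non-converged voxels stay flagged `NA`. `voi_statistics()`
reduces maps to the six per-patient diffusion features: means and
single-voxel minima of ADC and D (the "min" statistic granularity is the
single voxel — a choice, since coarser definitions such as small-ROI minima
would need an unstated kernel), and VOI means for $D^*$ and $f$, reported in
the conventional $10^{-3}$ mm²/s unit.

# PET metabolic metrics

`segment_mtv()` implements the fractional-SUVmax convention: SUVmax is the
maximum SUV inside the operator's seed ROI, and the metabolic tumor volume
is the set of voxels with SUV ≥ 40% of SUVmax (fraction configurable). Two
details are deliberate choices:

* **Connectivity.** The mask is restricted to the 26-connected component
  containing the SUVmax voxel, so a hot structure elsewhere inside a loose
  ROI cannot inflate MTV.
* **SUVmean over the metabolic mask.** SUVmean (and hence TLG =
  SUVmean × MTV) is computed over the segmented metabolic volume — the
  "entire tumor" in the threshold sense — which is the definition under
  which the published worked examples (9.35 × 34.94 = 326.69 g;
  7.92 × 10.1 = 79.99 g) are exact products.

The TLG identity, MTV monotonicity in the threshold, and invariance of MTV
under positive rescaling of SUV are enforced by property tests. No
partial-volume correction is applied.

# Diagnostic statistics

* `chi_square_2x2()` — Pearson chi-square **without** Yates continuity
  correction: the uncorrected statistic reproduces the printed MRI-node
  p = 0.009 on the 61/17/8/9 table (the corrected one gives ≈ 0.02).
* `binary_test_diagnostics()` — sensitivity/specificity in percent and the
  one-cutpoint AUC (sens + spec)/200 of a binary reading.
* `group_compare()` — Shapiro-Wilk screen at α = 0.05 per group selects
  Welch t vs Mann-Whitney U; the choice is reported. The screen is a
  design decision (the analysis convention names only "t-test or
  Mann-Whitney U").
* `roc_continuous()` — empirical ROC by rank statistics (AUC = U/(n₁n₀),
  ties one half), DeLong variance for the CI, Youden-index cutoff reported
  as the midpoint between adjacent observed values with ties broken toward
  higher specificity. Direction is explicit: protective markers (Dmin,
  Dmean — lower values predict metastasis) are auto-oriented so reported
  AUCs are ≥ 0.5 with the orientation noted.
* `delong_compare()` — paired DeLong test via structural components;
  identical predictions give p = 1 with a warning rather than 0/0.
* `fit_logistic()` — ML logistic regression with Wald chi-square inference
  (W = (β/SE)², df 1), separation detection, and collinearity errors that
  name the offending variables.
* `icc_two_rater()` — ICC(2,1): two-way random, absolute agreement, single
  measures. The form is a design decision; absolute agreement is chosen
  because the two radiologists' measurements are meant to be
  interchangeable, so a systematic shift should count against agreement.
  0.8–1 is labeled "high".
* `spearman_matrix()` — rank correlations with t-approximation p-values.

## The combined model

`build_combined_model()` reproduces the two-stage selection: univariate
logistic screening at p < 0.1, then forward stepwise entry at the
Bonferroni-corrected threshold α/n (0.05/10 = 0.005 for the full analysis;
0.05/3 ≈ 0.0167 for the PET-negative subset where the candidate panel is
MTV, TLG, Dmin). The Bonferroni divisor counts the quantitative imaging
feature panel, following the published correction convention; it is an
explicit argument. Entry is driven by the candidate's Wald p in the
expanded model; there is no removal step (the selection is entry-driven).
Every decision is logged in an audit trail. The final model's in-sample
linear predictor is scored by ROC and can be compared to single features
with the DeLong test — deliberately *in-sample*, preserving (and
documenting) the optimism of evaluating a model on its training data, as
the original procedure does.

# The synthetic-data module

## What it emulates

* **DWI phantoms** (`make_dwi_phantom()`): ellipsoidal lesion
  (D = 0.90×10⁻³ mm²/s, D* = 42.58×10⁻³, f = 0.16 by default — the
  node-negative tumor means) in a background of more diffusive, less
  perfused tissue (D = 1.40×10⁻³, D* = 20×10⁻³, f = 0.05, a generic pelvic
  soft-tissue setting), signals from the forward model on the 14-value
  schedule, **Rician** noise (magnitude of signal plus complex Gaussian,
  per-channel sd = `noise_sigma`·S0, default 2%) — magnitude MR data are
  Rician, and the resulting noise floor at high b is exactly what stresses
  an IVIM fitter. Truth maps are returned for recovery tests.
* **PET phantoms** (`make_pet_phantom()`): truncated-Gaussian uptake
  profile (width 0.5 in normalized ellipsoidal radius) from `suv_peak`
  (default 15.35 g/cm³) to background, so the 40% iso-contour encloses an
  analytically known strict subvolume — making MTV segmentation a real
  test rather than a mask-copy (`analytic_isocontour_volume()` is the
  oracle).
* **Cohorts** (`make_cohort()`): 78 node-negative / 17 node-positive
  patients; each feature drawn per class from a truncated normal (inverse
  CDF truncation at 0, and at 1 for f — no rejection loop, well-defined
  even for TLG-scale sds) with the class-conditional means/sds of the
  study cohort; PET node calls Bernoulli(9/78 | 10/17), MRI calls
  Bernoulli(17/78 | 9/17); TLG recomputed as SUVmean × MTV after the
  draws so the defining identity holds patient-wise.

## What it does not emulate

Only marginal per-class summaries are published, so **no inter-feature
covariance is imposed** beyond the TLG identity (pooled rank correlations
are insufficient to reconstruct a class-conditional joint distribution, and
guessing one would manufacture structure). Cohorts therefore carry less
joint signal than the real data — e.g. a real cohort's correlated
SUV/volume features would reinforce each other in a multivariate model,
drawn cohorts cannot. Likewise per-patient ADCmin can exceed ADCmean
across *different* draws (they are independent marginals, not derived from
one map), truncation shifts the effective means slightly upward for
features with large sd/mean ratios (MTV ~ +1.6), and acquisition physics
(motion, distortion, coil profiles) are out of scope. Passing tests on
these cohorts demonstrate the *statistical machinery*, not clinical
performance.

# Numerical choices

* Log-linear steps solved by closed-form weighted least squares
  (`lm.wfit`), weights ∝ signal².
* Full-fit optimizer: L-BFGS-B, `factr = 1e4`, ≤ 500 iterations; segmented
  fallback on any failure or residual increase.
* Logistic convergence: IRLS tolerance 1e-8; separation flagged when
  fitted probabilities pin to 0/1 or |β| > 15.
* ROC cutoffs: midpoints between adjacent observed marker values
  (sentinels beyond the range close the curve); Youden ties resolved
  toward specificity.
* Chi-square refuses zero margins (pointing to exact tests) instead of
  returning NaN.
* All generators take explicit integer seeds; at `noise_sigma = 0` the
  noise path is skipped entirely so outputs equal the forward model
  bit-for-bit.

# Problem sizes in the test battery

The parameter-recovery battery fits an ~860-voxel lesion phantom
(40×40×24 grid, 2 mm voxels) noiselessly, a 1000-replicate single-voxel
Monte-Carlo at 2% Rician noise, calibrates the DeLong test's type-I error
on 500 null simulations of 200 patients, and measures the combined-model
dominance property across 100 default cohorts — sizes chosen so each
check is statistically meaningful while the whole battery stays a
desk-scale computation.

# Known limitations

* Equivalence with the vendor IVIM toolbox cannot be asserted (its
  algorithm is unpublished); the package guarantees internal
  forward/inverse consistency instead.
* The segmented fit's ≤ 1% recovery guarantee degrades for
  $D^* \lesssim 20\times10^{-3}$ mm²/s at the default threshold, as
  analyzed above.
* Whether the reported per-patient $f$ and $D^*$ are VOI means or another
  statistic is unstated in the source convention; VOI means are used.
* ICC confidence intervals are not computed (point estimates only).
* The combined model is evaluated in-sample by design; no cross-validation
  is offered because the procedure being reproduced had none.
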