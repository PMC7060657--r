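# petivim

Quantitative PET-IVIM analysis for predicting pelvic lymph-node metastasis
in cervical cancer from simultaneous PET/MR examinations.

Preoperative lymph-node assessment guides the choice between surgery and
chemoradiotherapy, but visual PET reading of nodes is specific while
insensitive. The quantitative descriptors of the *primary tumor* carry
complementary signal: metabolic burden from PET and tissue
microstructure/perfusion from multi-b-value diffusion MRI. `petivim`
implements the full analysis chain:

* **IVIM fitting.** Voxelwise bi-exponential decomposition
  `S(b)/S(0) = f·exp[−b(D* + D)] + (1−f)·exp(−bD)` of multi-b-value DWI
  into pure diffusion D, pseudo-diffusion D\* and perfusion fraction f,
  via the segmented (high-b asymptotic) fit or a full bounded nonlinear
  least-squares fit, plus the mono-exponential ADC. VOI reduction yields
  the per-patient features ADCmean, ADCmin, Dmean, Dmin, D\*, f.
* **PET metabolic metrics.** SUVmax, SUVmean, metabolic tumor volume by
  the 40%-of-SUVmax threshold (26-connected, seeded at the peak) and
  total lesion glycolysis TLG = SUVmean × MTV.
* **Diagnostic statistics.** 2×2 node diagnostics with uncorrected
  Pearson chi-square; empirical ROC with Youden-index cutoffs and DeLong
  variance/comparison tests; Welch-t / Mann-Whitney group comparisons with
  a Shapiro-Wilk screen; Spearman matrices; two-rater ICC(2,1); and the
  two-stage (univariate p < 0.1, forward stepwise at the
  Bonferroni-corrected α) logistic model combining tumor features with the
  PET node call.
* **Synthetic data.** Ellipsoidal PET/DWI lesion phantoms with
  analytically known iso-contour volumes and Rician DWI noise, and patient
  cohorts (78 node-negative / 17 node-positive by default) reproducing the
  study's class-conditional feature summaries — so the entire pipeline is
  testable without patient data.

## Worked example

```r
library(petivim)

# PET node reading of a 95-patient cohort as a 2x2 table
binary_test_diagnostics(contingency_2x2(tn = 69, fp = 9, fn = 7, tp = 10))
#> $sensitivity  58.82353
#> $specificity  88.46154
#> $auc          0.7364253

# noiseless IVIM round trip on the 14-value b-schedule
b <- default_b_values()
fit_ivim_segmented(ivim_signal(b, D = 0.9e-3, D_star = 42.58e-3,
                               f = 0.16, S0 = 1000), b)[c("D", "D_star", "f")]
#> D 0.0009   D* 0.04259   f 0.16

# synthetic cohort -> combined prediction model
co <- make_cohort(cohort_spec(seed = 1))
m <- build_combined_model(co)
cat(m$audit, sep = "\n")
#> univariate screen at p < 0.1: 6 of 12 candidates retained (mtv, tlg,
#>   adc_min, d_min, pet_node_positive, mri_node_positive)
#> enter pet_node_positive (p = 0.0004178 < 0.005)
#> enter mri_node_positive (p = 0.002248 < 0.005)
#> stop: best remaining candidate mtv has p = 0.01685 >= 0.005
m$roc
#> <roc_result> AUC 0.804 (95% CI 0.682-0.926), cutoff -2.072
#>   (>= cutoff predicts positive), sens 82.35%, spec 66.67%, J = 0.490
```

The first call reproduces the published PET node diagnostics exactly
(sensitivity 58.82%, specificity 88.46%, binary AUC 0.736). The segmented
fit recovers the generating IVIM parameters of a noiseless voxel to
machine-level accuracy. The cohort example shows the selection audit: the
univariate screen retains six candidates, forward entry at the
Bonferroni-corrected threshold 0.05/10 = 0.005 admits two, and the
combined model's in-sample AUC (0.804) exceeds each single feature's on
the same data.

A thin command-line umbrella over the same functions ships in
`inst/cli/petivim.R`:

```sh
petivim=$(Rscript -e 'cat(system.file("cli/petivim.R", package = "petivim"))')
Rscript $petivim simulate phantom --config spec.yaml --out phantom/
Rscript $petivim fit-ivim --dwi phantom/dwi.nii.gz --bvals phantom/bvals.txt \
        --mask phantom/voi.nii.gz --out maps/
Rscript $petivim pet-metrics --suv phantom/suv.nii.gz --roi phantom/voi.nii.gz \
        --out metrics.csv
Rscript $petivim predict --cohort cohort.csv --out report.json
```

Volumes are NIfTI-1 with b-value sidecars (plain text or JSON); cohorts
are CSV in a fixed schema; reports are JSON.

## Documentation

The methods vignette (`vignettes/petivim-methods.Rmd`) describes the
models, every tunable parameter with units and defaults, what the
synthetic-data generator does and does not emulate, numerical choices, and
known limitations.
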