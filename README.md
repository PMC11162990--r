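# ngdwi — non-Gaussian diffusion MRI modeling and whole-tumor histogram analysis

`ngdwi` re-implements, as a tested R package plus a numbered analysis
workflow, a complete diagnostic-imaging pipeline for multi-b-value
diffusion-weighted MRI (DWI) of bladder tumors: voxel-wise fitting of five
non-Gaussian diffusion models alongside the conventional apparent diffusion
coefficient (ADC), whole-tumor first-order histogram radiomics, and the full
diagnostic-model-building and evaluation chain used to discriminate
muscle-invasive from non-muscle-invasive disease and high from low
histological grade. Because no patient data are public, the package ships a
synthetic phantom cohort generator with known ground truth, so every stage
is exercised end to end.

It is written for imaging scientists who want a transparent, fully scripted
reference implementation of this analysis family — every numeric step is a
documented exported function with unit tests against independent oracles.

## The models

With diffusion weighting `b` (s/mm²) the six signal models are

| Model | Signal equation | Metrics |
|---|---|---|
| mono-exponential | S = S₀·exp(−b·ADC) | ADC |
| IVIM | S = S₀·[f·exp(−b·D*) + (1−f)·exp(−b·D)] | f, D, D* |
| DKI | S = S₀·exp(−b·D + K(bD)²/6) | K, D |
| SEM | S = S₀·exp(−(b·DDC)^α) | α, DDC |
| FROC | S = S₀·exp(−D·μ^{2(β−1)}·(γG_dδ)^{2β}·(Δ − (2β−1)/(2β+1)·δ)) | β, μ, D |
| CTRW | S = S₀·E_α[−(bD)^β] | α, β, D |

where E_α is the Mittag-Leffler function, evaluated here on the negative
real axis to ≤1e−8 relative error (power series plus spectral-integral
quadrature; see the methods vignette). The 13 non-Gaussian metrics plus ADC
give 14 metric maps; 18 first-order histogram features per map give the
252-feature vector per participant.

The statistical chain follows the clinical-study design: two-rater ICC(2,1)
agreement filter at 0.80 → per-model LASSO with stratified 10-fold CV →
unpenalized logistic refit with Wald p-values → pooling of p < 0.05 features
→ Spearman redundancy pruning (|ρ| > 0.70 drops the lower-ICC member) →
combined logistic model → held-out evaluation with DeLong AUC confidence
intervals and paired tests, Youden operating points, decision-curve
analysis, Hosmer-Lemeshow and bootstrap calibration error.

## Worked example

```r
library(ngdwi)
sch <- default_scheme()                     # the 11 b-values, 0-2500 s/mm^2

# one voxel: simulate a CTRW decay, add Rician noise, fit it back
truth <- c(S0 = 100, D = 1.0e-3, alpha = 0.9, beta = 0.9)
clean <- signal_model("CTRW", truth, sch)
noisy <- as.vector(add_rician_noise(array(clean, c(1, 1, 1, 11)), snr = 50, seed = 1))
fit_voxel("CTRW", noisy, sch)$par
#>           S0            D        alpha         beta
#> 98.793364898  0.001034851  0.735900571  0.994994078

# a full synthetic two-class cohort through the whole diagnostic chain
cohort <- generate_cohort(100, 25, spec0 = group_param_spec(),
                          spec1 = spec_mibc_like(), seed = 12)
report <- run_pipeline(cohort, pipeline_config(seed = 12))
report
#> diagnostic pipeline report
#>   features: 14 maps x 18 = 252 (252 retained at ICC filter)
#>   cohorts: 200 training / 50 testing
#>   CTRW     test AUC 1.000 (1.000-1.000), 6 features
#>   ...
#>   Combined test AUC 1.000 (1.000-1.000), 7 features
```

The per-voxel numbers are the recovered CTRW parameters (diffusivity in
mm²/s; the temporal and spatial fractional orders are dimensionless); the
report lists held-out AUC with DeLong 95% CI per diffusion model and for
the combined model.

## Analysis workflow

`analysis/01_simulate.R` … `05_evaluate.R` run the full study analogue on
three synthetic cohorts (invasion-like contrast, grade-like contrast, and a
null control), writing manifests, ICC reports, model cards (feature /
coefficient / p-value tables), held-out predictions, evaluation metrics,
DeLong comparison matrices and decision curves under `results/`. Bulky
regenerable intermediates (per-patient feature tables, example map TSVs) go
under `scratch/`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's main computation from scratch: it generates an
effect cohort and a null cohort at the given seed, runs the complete
feature → ICC → LASSO → logistic → pruning → combined-model → held-out
evaluation chain on both, prints the two reports, and writes the JSON
result object to `--out`.
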