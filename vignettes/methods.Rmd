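---
title: "Methods: non-Gaussian diffusion modeling and diagnostic-model building"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: non-Gaussian diffusion modeling and diagnostic-model building}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ngdwi)
```

# Overview

`ngdwi` implements a complete quantitative-DWI diagnostic pipeline for
bladder-tumor characterization: six signal models fitted voxel-wise to an
11-b-value acquisition (0–2500 s/mm²), whole-tumor first-order histogram
features, a two-rater reliability filter, LASSO-plus-logistic diagnostic
model building, and held-out evaluation. This vignette records the model
assumptions, the numerical choices, and the design decisions that were
genuinely open — the clinical study this analysis family comes from used
unpublished in-house fitting software and appendix tables that are not
public, so several conventions had to be fixed here and are documented as
this package's own choices.

# Signal models and their assumptions

All models describe the decay of the magnitude MR signal with diffusion
weighting `b` in a single voxel; all are scalar-`b` (no directional
encoding) and share `S0`, the signal without diffusion weighting.

* **Mono-exponential (ADC)** assumes Gaussian diffusion. By default the ADC
  map is computed from b = 0 and 800 s/mm² only, matching the conventional
  two-b DWI protocol whose map this package's `ADC` stands in for; a
  full-grid mono-exponential fit would also be biased by the Rician noise
  floor at b ≥ 1500 where the true signal approaches the noise level.
* **IVIM** adds a microvascular pseudo-diffusion compartment (fraction `f`,
  coefficient `D*`). It is fitted on b ≤ 1000 s/mm² by default because the
  bi-exponential form ignores kurtosis effects that dominate beyond that.
* **DKI** expands the log-signal to second order; its quadratic form is
  only a valid decay below roughly b = 3/(K·D), beyond which the parabola
  turns upward. This is a property of the model, not of the fit; the
  package evaluates the equation as written, and the tests restrict
  monotonicity checks to the validity regime.
* **SEM** (stretched exponential) uses S = S₀·exp(−(b·DDC)^α). One
  published form places the sign inside the power, which is complex-valued
  for α < 1; the standard real form is implemented.
* **FROC** (fractional-order calculus) is written in gradient parameters
  (γ, G_d, δ, Δ). Acquisition timing is rarely reported; the default is
  δ = 20 ms, Δ = 40 ms with γG_dδ derived per b-value from
  b = (γG_dδ)²(Δ − δ/3), which makes β = 1 collapse exactly to exp(−bD).
  **Identifiability caveat:** with a single (δ, Δ) the b-space decay
  depends on D and μ only through D·μ^{2(β−1)}, so μ cannot be estimated
  from the data; `fit_voxel()` pins μ at the configured spatial constant
  (default 5×10⁻³ mm) and estimates (S0, D, β). A freely "fitted" μ would
  be an initialization artifact.
* **CTRW** (continuous-time random walk) uses the Mittag-Leffler decay
  S = S₀·E_α[−(bD)^β], with temporal (α) and spatial (β) fractional orders
  capturing waiting-time and step-length heterogeneity.

## Mittag-Leffler numerics

`mittag_leffler(alpha, z)` evaluates E_α(z) for 0 < α ≤ 1 and z ≤ 0, the
completely monotone branch needed by CTRW. Two regimes:

* **Power series** Σ z^k/Γ(αk+1) for |z| ≤ (7/α)^α. Each term is formed
  directly from `lgamma` (no multiplicative recursion), so per-term error
  stays near one ulp; the threshold keeps the largest term small enough
  that summed rounding cannot breach 1e−10.
* **Spectral integral** elsewhere: after substituting s = r^α, E_α(−x) =
  sin(απ)/(απ) ∫₀^∞ exp(−x^{1/α} s^{1/α}) / (s² + 2s·cos(απ) + 1) ds,
  integrated adaptively on (0,1) and (1,∞) with the split at the kernel
  peak so the near-pole at α → 1 is resolved.

An asymptotic expansion was deliberately **not** used: its
optimal-truncation error ~exp(−x^{1/α}) cannot reach 1e−8 for α near 1 at
moderate |z|. The implementation is verified against a 60-digit reference
grid (α ∈ {0.3,…,1.0} × |z| ≤ 50) computed by two independent
extended-precision routes that agree to < 1e−10; the suite requires ≤ 1e−8
relative error everywhere on the grid.

# Voxel-wise fitting

The estimation strategy (unpublished in the source study) is bounded
nonlinear least squares via `stats::nlminb` on unit-rescaled parameters,
initialized from a closed-form log-linear mono-exponential fit; shape
parameters start at α = β = 0.9, K from a quadratic log-fit, f at the
intercept excess of the segmented IVIM stage. IVIM is segmented: tissue D
from the log-linear tail (b ≥ 200), then (f, D*) with D fixed, then a joint
bounded refinement. Up to three deterministic seed-jittered restarts run
when the first attempt does not converge. Bounds are physiologic:
ADC/D/DDC ∈ (10⁻⁶, 5×10⁻³) mm²/s, D* ∈ (3×10⁻³, 0.1) mm²/s, f ∈ [0, 0.5],
K ∈ [0, 3], α, β ∈ (0.01, 1], μ ∈ (10⁻⁴, 0.02) mm; a soft penalty keeps
D* ≥ 1.2·D so the two IVIM compartments cannot swap roles. Degenerate
voxels (non-positive b = 0 signal) are flagged, set to bound midpoints, and
emitted as NA so they drop out of histogram analysis. An optional
first-moment Rician correction (`rician_sigma`) replaces model predictions
by √(S² + σ²) when the noise level is known; it is off by default and not
needed to meet the recovery tolerances at SNR 50.

Maps are computed in mm²/s internally and emitted in 10⁻³ mm²/s (µm²/ms),
the unit convention of the field's result tables (whose printed footnote
"×10⁻³ µm²/ms" is dimensionally inconsistent and is read here as
10⁻³ mm²/s).

# Histogram features

Eighteen first-order features per metric map — energy, total energy (TE =
voxel volume × energy), entropy, minimum, 10th/90th percentile, maximum,
mean, median, IQR, range, mean absolute deviation, robust MAD (within the
10–90 percentile band), RMS, skewness, kurtosis (non-excess), variance,
uniformity. The exact 18-feature list of the source study sits in an
unavailable appendix; this is the standard IBSI-aligned first-order set
with standard deviation omitted as redundant with variance, and it contains
every feature name that appears in the study's printed tables. Conventions:
population (biased) moments; skewness and kurtosis of a zero-variance
sample are 0; percentiles use linear interpolation between closest ranks
(R type 7); entropy/uniformity discretize the in-VOI range into 64
equal-width bins (the study's binning is unknown; 64 is scale-free across
metrics with heterogeneous units and is configurable). 14 maps × 18
features = 252 columns, always. Necrosis/stalk exclusion is honored via an
optional exclusion mask; no automatic detection is attempted (it was manual
in the clinical workflow).

# Reliability filter

Two raters' feature tables are compared with ICC(2,1): two-way random
effects, absolute agreement, single measurement — the default reporting
convention for segmentation reproducibility (the study names only "two-way
random effects"; absolute agreement is this package's documented reading).
Features with ICC < 0.80 are excluded. Zero-variance features return a
flagged NA and are dropped.

# Model building

Per diffusion model, LASSO (binomial, glmnet) on the ICC-retained features:
features standardized once on the training cohort, stratified 10-fold CV
with seed-fixed folds, λ at minimum mean CV deviance over a 100-point log
grid down to 10⁻³·λ_max (1-SE rule available). Selected features enter an
unpenalized logistic refit; Wald p < 0.05 features pool across models;
pairs with |Spearman ρ| > 0.70 lose their lower-ICC member (greedy,
worst-pair-first, with an audit trail); survivors form the combined
logistic model. Perfect or quasi-separation — likely at desk-scale n with
strong contrasts — is detected and the refit falls back to a
ridge-stabilized fit (λ = 0.01 on standardized features) whose Wald
covariance is computed in the standardized space and mapped back, which
stays well-conditioned even when exactly proportional features (energy vs
total energy at unit voxel volume) are co-selected. An empty significant
pool — the expected outcome on a null cohort — degrades the combined model
to intercept-only, flagged in the report, rather than failing the run.

# Evaluation

AUC is the Mann-Whitney pair statistic (ties half-weighted); DeLong
structural components are computed via midranks, giving the 95% CI on the
AUC scale (clipped to [0, 1]) and the paired test between correlated
models. The operating point maximizes the Youden index over observed
scores, ties broken toward sensitivity. Decision curves use
NB(p_t) = TP/N − (FP/N)·p_t/(1−p_t) on a 0.01–0.99 grid. Hosmer-Lemeshow
uses deciles of predicted risk, df = groups − 2 (the convention calibrated
for model-fitted probabilities; the suite's null simulation therefore fits
a logistic model before testing). The bootstrap calibration MAE averages,
over seeded resamples, the mean absolute gap between a 10-bin
observed-frequency curve (linear interpolation between bin centers) and the
identity on a fixed grid spanning the central 90% of predicted
probabilities; with constant predictions the curve degenerates to a point
and the result is flagged. The study's printed MAEs (0.020/0.010/…) depend
on its patient data and a smoother it does not name; this MAE is a
documented analogue, not a reproduction.

# Synthetic cohorts: what they emulate, and what not

`generate_cohort()` builds ellipsoidal tumors (semi-axes 3–6 voxels at desk
scale; ~140–900 voxels per VOI), optional interior "necrosis" ellipsoids
exported as exclusion masks, per-patient ground-truth maps drawn from
per-class distributions (patient-level mean plus voxel-level scatter,
one-pass 6-neighbor smoothing for spatial texture), a second-rater mask by
random boundary toggling constrained to Dice ≥ 0.85, and optionally
rendered noisy DWI. Noise is Rician, √((S+σε₁)² + (σε₂)²), with SNR 50 at
b = 0 by default (the study reports no noise characteristics; 50 is a
typical pelvic 3 T figure). Between-class contrasts follow the direction
the study reports: the invasion-like class lowers all diffusivity-map means
by 30% and adds a right-skew mixture (weight 0.25, shift 3 within-tumor
SDs) on diffusivity and temporal-order maps; the grade-like class raises
the perfusion fraction by 0.05 and mildly lowers diffusivity. These values
were fixed a priori as a plausible strong contrast and are not tuned.

What a green end-to-end test establishes: the statistical chain orders,
filters, selects, prunes, refits and evaluates exactly as specified, finds
designed contrasts, and stays at chance on null cohorts. What it does not
establish: clinical effect sizes (the phantom contrast is far cleaner than
patient data — held-out AUCs near 1.0 are expected here and say nothing
about the study's 0.915), anatomically realistic geometry, scanner
artifacts, or inter-scanner differences beyond seed streams.

Cohort-level runs extract features from the ground-truth maps by default
(`fit_maps = FALSE`): voxel-wise fitting of 6 models × 250 patients × 20
replicates is far outside any reasonable test budget, and the fitting stage
is validated separately — noiseless round-trips to ≤ 0.1%, median bias at
SNR 50 within 5% (rate) / 10% (shape) over 1000 voxels, and a small
full-fit pipeline test (`fit_maps = TRUE`) that runs render → noise →
six-model fit → features → models → evaluation end to end.

# Known limitations

* FROC's μ map is a convention, not a measurement (see above); its
  histogram features are only meaningful across datasets sharing the
  convention.
* The greedy redundancy pruning is order-dependent in principle; it is
  verified against exhaustive search on small instances but is not globally
  optimal in general.
* The ridge fallback's Wald p-values are approximations under separation;
  they keep the pipeline running and flagged rather than being exact
  inference.
* NIfTI I/O is out of scope in this build (no NIfTI-capable R package in
  the dependency environment); volumes are in-memory arrays with a
  plain-text TSV exchange format carrying grid and voxel-size metadata.
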