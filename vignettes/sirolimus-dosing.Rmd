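---
title: "Population pharmacokinetics and starting-dose simulation for sirolimus in children"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population pharmacokinetics and starting-dose simulation for sirolimus in children}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sirodose)
```

## The problem

Children with tuberous sclerosis complex are treated with sirolimus, an
mTOR inhibitor with a narrow maintenance window (5–15 ng/ml trough) and
large pharmacokinetic variability. Therapeutic drug monitoring adjusts the
dose *after* the first measured trough; the starting dose has to come from a
model. `sirodose` implements the full pharmacometric workflow on sparse
pediatric TDM data: a hierarchical concentration model, maximum-likelihood
estimation, covariate selection, model qualification, and Monte-Carlo
starting-dose simulation, plus Hardy–Weinberg checks for the accompanying
pharmacogenetic panel.

## Structural model and its assumptions

The observed parameter set — apparent oral clearance CL/F, apparent volume
V/F, and a first-order absorption constant Ka — corresponds to a
one-compartment model with first-order absorption and elimination and no lag
time:

$$C(t) = \frac{D\,k_a}{V\,(k_a-k_e)}\left(e^{-k_e t}-e^{-k_a t}\right),
\qquad k_e = \frac{CL/F}{V/F}.$$

Assumptions worth stating explicitly:

* **One compartment, linear elimination.** Sirolimus has deep tissue
  distribution; a one-compartment description is a deliberate simplification
  that sparse trough data cannot improve upon.
* **Bioavailability is folded in.** Only apparent parameters (CL/F, V/F) are
  identifiable from oral data; F is never modelled separately.
* **Ka is fixed at 0.485 h⁻¹.** Trough-only sampling carries no absorption
  information, so Ka is a structural constant, not an estimate.
* **Units.** Internally amounts are µg, volumes L, times h, so
  concentrations are µg/L ≡ ng/ml; doses cross the API boundary in mg and
  are converted exactly once. When $k_a$ and $k_e$ coincide within 1e-10 the
  analytic limit $(D\,k_a t/V)e^{-k_a t}$ replaces the two-exponential form.

Multiple doses superpose linearly, and the steady-state trough has the
closed accumulation form used throughout the simulation layer; its
equivalence with long explicit superposition is part of the test suite.

## Hierarchical (mixed-effects) model

Typical values scale allometrically with weight around a 70 kg standard,
with fixed exponents 0.75 (CL/F) and 1 (V/F). Each child gets log-normal
random effects on both parameters — independent, since only the two
diagonal variances are reported for this drug–population pair — and
observations carry combined proportional + additive noise:

$$OBS_{ij} = IPRED_{ij}(1+\varepsilon_1) + \varepsilon_2 .$$

A note on conventions: the reference variability values (`omega2_cl` 0.066,
`omega2_v` 0.003, `sigma2_prop` 0.312, `sigma2_add` 1.249) are treated as
**variances**, the dominant reporting convention of the estimation software
used in this field; source tables are often ambiguous between ω and ω².

### FOCE-I estimation

`ofv_foce()` computes, per subject, the conditional mode of
$(\eta_{CL},\eta_V)$ by quasi-Newton minimisation of the joint
−2 log-density (analytic gradient, started at 0, gradient tolerance 1e-8),
then applies a Laplace-type correction using the exact curvature of the
joint objective at the mode (central finite differences of the analytic
gradient, with a Gauss–Newton $G'WG+\Omega^{-1}$ fallback when the exact
Hessian is not positive definite). The residual variance is evaluated at the
η-dependent individual prediction — the "interaction" of FOCE-I. The OFV
keeps its $n\log 2\pi$ constants, so as $\omega^2 \to 0$ it converges to the
exact fixed-effects −2 log-likelihood; the suite asserts agreement with a
40-node Gauss–Hermite quadrature oracle on small instances.

`fit_pk()` minimises the OFV over $(\theta_{CL}, \theta_V, \omega^2_{CL},
\omega^2_V, \sigma^2_{prop}, \sigma^2_{add})$ plus covariate coefficients.
Numerical choices:

* positives are optimised on the log scale; variances have a soft floor at
  1e-8 and estimates landing there are flagged as boundary hits rather than
  errors (near-zero variance components are legitimate in this population);
* three deterministically jittered starts (±0.4 on the log scale) guard
  against local minima; reported non-convergence is re-checked by a restart
  from the optimum before being flagged;
* standard errors come from the central finite-difference Hessian of the
  OFV at the optimum and are reported as 100·SE/estimate.

### Covariate machinery

Covariates act multiplicatively on a typical value in one of three forms:
genotype factor $\theta^x$ (x a 0/1 indicator), power of a median-centred
continuous covariate $(\text{cov}/\text{ref})^\theta$, or linear
$1+\theta\,\text{cov}$. `covariate_search()` does forward inclusion (largest
ΔOFV > 3.84, repeatedly; ties broken by candidate order) followed by one
backward pass (removal must raise the OFV by > 6.64 to keep a covariate),
returning the per-candidate ΔOFV ledger so the selection is auditable.

## Model qualification

* **Bootstrap** (`bootstrap_pk()`): resampling is by *subject* — the
  exchangeable unit in hierarchical data — with percentile intervals and
  bias defined against the median, $100(\tilde\theta-\hat\theta)/\hat\theta$.
  Failed replicates are excluded and counted; >50% failures warns.
* **pcVPC** (`vpc_pk()`): simulated replicates at the observed design;
  observed and simulated concentrations are prediction-corrected by the
  bin-median population prediction over the subject's own. Defaults: 1,000
  simulations, 4 quantile-based time bins (sparse data cannot support more).
  The reported `fraction_inside` is calibrated (≈95% on self-simulated
  data), which the suite checks.
* **Residuals** (`residual_diagnostics()`): IWRES uses the η-mode individual
  prediction; WRES uses the first-order (η = 0) linearisation with the
  model-implied covariance, since no particular weighted-residual flavour is
  canonical for this analysis.

## Starting-dose simulation

`pta_grid()` simulates virtual patients (default 1,000 per cell) over
weights {5, 10, 20, 30, 40, 50, 60} kg, daily doses 0.01–0.10 mg/kg/day and
both regimens (QD τ = 24 h; BID τ = 12 h with the daily dose split evenly),
evaluating each patient's *analytic* steady-state trough — the accumulation
formula, not a long explicit simulation. PTA is the fraction of troughs
inside 5–15 ng/ml, bounds inclusive. Each weight/regimen cell derives its
own deterministic sub-seed from the master seed, so results do not depend on
cell order, and all candidate doses within a cell are evaluated on the same
virtual population (common random numbers — troughs are linear in dose), so
dose comparisons are not blurred by independent Monte-Carlo noise.

Two design decisions deserve emphasis:

* **Residual error is off by default.** PTA describes the distribution of
  *true* model troughs; adding one draw of assay/within-subject noise per
  trough is available (`include_residual = TRUE`) because published
  concentration intervals may include it, but it answers a different
  question ("what would a measured trough show?").
* **The selection rule is an explicit approximation.** Published dose
  recommendations in this area weigh the target probability together with a
  95% concentration interval without operationalising the trade-off.
  `recommend_dose()` implements a
  reproducible default — maximise the minimum PTA over the bracket's two
  endpoint weights, ties to the lower dose — and always returns the full
  audit table so stricter safety rules can be layered on. The lightest
  once-daily bracket (5–10 kg → 0.10 mg/kg/day) is robust to this choice;
  heavier brackets and the twice-daily table can shift by one dose step
  under alternative rules, which is why only the audit table, not the full
  published recommendation table, is treated as reproducible.

Doses are not rounded to practical tablet strengths.

## Synthetic data: what it does and does not emulate

`generate_cohort()` emulates the motivating cohort: ~15 children, weights
log-uniform on 10–50 kg (the reported range; log-uniform rather than
resampling reported summary statistics), weight-based oral dosing continued
two weeks — comfortably past ten elimination half-lives for any weight in
range — and trough-only sampling on three pre-dose occasions, which is how
TDM data actually look. A `"rich"` design (1, 2, 4, 8, 12, 24 h after the
last dose) exists because trough-only sparse data cannot identify the
absorption side or separate the two variance sources; estimation studies use
it. The default daily dose of 0.05 mg/kg/day places typical troughs
mid-window across the weight range. `simulate_observations()` is the exact
generative counterpart of the estimator: one η pair per subject, one
combined residual draw per observation, truncation at zero.

What the generator does **not** emulate: assay quantification limits,
within-subject variability over occasions, non-adherence, drug–drug
interactions, or covariate–weight correlations. Passing tests on synthetic
data therefore demonstrate the estimator/simulator contract, not clinical
performance on real TDM data.

## Identifiability and known limitations

Replicated generate/fit cycles under the reference model recover the
typical values tightly (medians within ~5%) and the clearance variance and
proportional residual variance within a factor of two. Two components are
weakly identified at realistic sample sizes: the volume variance (reference
value 0.003, essentially a boundary estimate — its own reported uncertainty
spans two orders of magnitude) and the additive residual variance, which
only matters near zero concentration where sparse designs have no samples.
Their estimates scatter widely across replicates and should be read as
nuisance parameters, not as biology. This mirrors the source analysis,
whose own bootstrap intervals for these components are extremely wide.

Other limitations: no multi-compartment or nonlinear elimination, no
inter-occasion variability, no off-diagonal ω covariance, no exact
(permutation) Hardy–Weinberg test — the Pearson chi-squared with 1 df and
no continuity correction is used deliberately, as it is the convention that
reproduces the published panel's P values from its printed counts.

## Problem sizes used by the test suite

The suite favours the smallest sizes at which each property is decisive:
quadrature-oracle comparisons on 2–3 subjects; replicated recovery at
4 × 16 subjects; the single-cohort recovery check at 100 subjects with six
post-dose samples; VPC calibration at 40–50 subjects with 300 simulations;
selection calibration over 20 replicate null datasets of 12 subjects;
dose-grid checks at 300–1,000 virtual patients per cell. These choices are
stated here so they can be revisited deliberately rather than rediscovered.
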