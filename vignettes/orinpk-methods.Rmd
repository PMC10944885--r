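---
title: "Population pharmacokinetics of oral ORIN1001: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population pharmacokinetics of oral ORIN1001: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

ORIN1001 is a first-in-class oral IRE1-alpha endoribonuclease inhibitor in
clinical development for advanced solid tumors. Its first-in-human study was
a small dose-escalation trial (25 patients, seven once-daily arms from 100 to
900 mg) with sparse sampling: a single dose observed for four days, then 21
daily doses with a day-21 profile. This package implements the complete
population-pharmacokinetic workflow for such a study — structural model,
hierarchical covariate model, FOCE estimation, stepwise covariate selection,
diagnostics, non-compartmental analysis and steady-state covariate impact
simulation — together with a synthetic-trial generator, because the patient
data themselves are confidential. Everything the package claims about its
own behaviour is established on synthetic trials generated from the fully
published final model.

## Structural model

Disposition is a two-compartment linear model with first-order elimination
from the central compartment and first-order absorption after a lag:

$$
\dot A_g = -k_a A_g,\qquad
\dot A_1 = k_a A_g - (k_{10} + k_{12})A_1 + k_{21}A_2,\qquad
\dot A_2 = k_{12}A_1 - k_{21}A_2,
$$

with $k_{10} = CL/V$, $k_{12} = CL_2/V$, $k_{21} = CL_2/V_2$. All clearances
and volumes are apparent (oral bioavailability $F$ is never separated; the
package treats $F = 1$ implicitly, as the parameters are reported as $CL/F$,
$V/F$, etc.). Predictions use the closed-form tri-exponential solution,
summed over doses by superposition; `predict_concentration()` returns ng/mL
for doses in mg and volumes in L. The hybrid constants satisfy
$\alpha + \beta = k_{10}+k_{12}+k_{21}$ and $\alpha\beta = k_{10}k_{21}$.
Steady-state quantities use the exact geometric accumulation of each
exponential term; the interval AUC is $\text{Dose}/CL$ identically, the
trough is the concentration $\tau$ hours post dose, and the peak is located
on a 0.05 h grid refined by golden-section search (the peak time has no
closed form under a lag).

Two numerical choices matter here:

* **Absorption-onset taper.** The lag model's hard cutoff at
  $t = t_\text{dose} + T_{lag}$ makes the likelihood non-differentiable in
  $T_{lag}$ whenever an individual lag crosses an observation time, which in
  turn destabilizes gradient-based estimation. The implementation multiplies
  each dose's contribution by $1 - e^{-400\,t_e^2}$ ($t_e$ = time since
  onset), a window that is numerically inactive beyond about 0.15 h after
  onset (factor $1-10^{-7}$ at $t_e = 0.2$ h) but keeps the objective smooth.
  The taper is part of the model everywhere — simulation, estimation and
  prediction use one code path.
* **Absorption/disposition degeneracy.** When $k_a$ collides with $\alpha$
  or $\beta$ (a removable singularity of the closed form), $k_a$ is nudged
  by one part in $10^8$; likewise for $\alpha \approx \beta$.

## Hierarchical layer

Individual parameters follow the exponential inter-individual variability
(IIV) model $P_{ij} = TVP_i \cdot \prod_k (c_{jk}/\text{ref}_k)^{\theta_k}
\cdot e^{\eta_{ij}}$ with $\eta \sim N(0, \Omega)$; covariate effects use the
power-of-median form, so a subject at the reference covariate value has
effect exactly 1. Residual error is proportional
($\mathrm{Var} = (\sigma_\text{prop} f)^2$), with additive and combined
variants available for base-model exploration. The packaged final model
(`orin_final_model()`) carries the published estimate set: typical values
$K_a$ 0.58 1/h, $T_{lag}$ 0.35 h, $V/F$ 26.21 L, $V_2/F$ 26.60 L, $CL/F$
1.07 L/h, $CL_2/F$ 0.75 L/h; exponents TBIL to $CL/F$ −0.46, LBW to $CL/F$
1.11, LDH to $V_2/F$ 0.99, LBW to $CL_2/F$ 2.21 with references TBIL 10.30
umol/L, LBW 45.13 kg, LDH 214 IU/L; diagonal $\omega^2$ of 0.049 ($V/F$),
0.067 ($CL/F$), 0.534 ($K_a$), 0.438 ($T_{lag}$); proportional residual SD
0.197. A non-diagonal $\Omega$ is supported through a log-Cholesky
parameterization but is off in the packaged model, which is reported
diagonal.

Derived covariates use the standard formulas behind the usual citations:
BMI, DuBois BSA, Janmahasatian lean body weight, Devine ideal body weight,
Deurenberg body-fat percentage, Cockcroft-Gault creatinine clearance
(creatinine converted from umol/L to mg/dL), and an adjusted weight
(IBW + 0.4 (WT − IBW)) applied only above BMI 25 kg/m², feeding an adjusted
Cockcroft-Gault clearance. They are isolated in `derive_covariates()` so
alternates can be swapped; the published cohort table serves as a
plausibility check.

## Estimation

`fit_poppk()` maximizes a FOCE-with-interaction approximation of the
marginal likelihood. Per subject, the conditional objective
$g(\eta) = -2\log p(y\mid\eta) - 2\log p(\eta)$ is minimized by damped
Gauss-Newton (finite-difference Jacobian of the prediction,
Levenberg-Marquardt damping, step cap) and the subject's contribution is the
Laplace/FOCE expression
$g(\eta^*) - q\log 2\pi + \log\det(\Omega^{-1} + J^\top V^{-1} J)$ with the
residual variance $V$ evaluated at the conditional mode (the "interaction").
Because the conditional objective can be multimodal in the absorption etas,
the inner optimizer finishes with basin-hopping kicks (±1 on each eta
coordinate, re-descending from promising kicks); consistent basin selection
is what keeps the outer objective smooth enough for quasi-Newton search. The
residual variance floors the prediction at $10^{-3}$ ng/mL so the
proportional-error model cannot degenerate as predictions approach zero.

The outer problem runs `nlminb` on transformed parameters (log typical
values, raw exponents, log variances or log-Cholesky factors, log sigma)
with generous box bounds, an explicitly computed central-difference gradient
(eta warm starts are frozen during gradient evaluation so the optimizer sees
a deterministic function), and a restart chain that accepts a stationary
point when a restart no longer moves the objective. Defaults: relative
objective tolerance $10^{-6}$, at most 500 outer iterations, inner tolerance
$10^{-7}$. Standard errors come from the numerical Hessian of the OFV
(covariance $2H^{-1}$), delta-method mapped to the natural scale; variance
components are reported on the variance scale. `AIC = OFV + 2p` and
`BIC = OFV + p log n`. The implementation is documented as FOCE with
interaction — a published equivalent of the proprietary FOCE-ELS flavor —
so objective values from other engines on other data are context, not
targets. Starting values are data-driven (`initial_estimates()`: $V/F$ from
dose over Cmax, $CL/F$ from dose over a trapezoidal AUC); the FOCE
approximation itself is validated against adaptive Gauss-Hermite quadrature
on one- and two-eta problems in the test suite (agreement well within 0.5%
of the OFV).

## Covariate workflow

`covariate_prescreen()` computes pairwise Pearson correlations and, for
pairs with $|r| > 0.5$ and $p < 0.05$, retains one member. The retention
rule (the published description leaves it open) keeps the covariate with the
stronger univariate OFV drop when tested alone on $CL/F$
(`univariate_scores()`); without scores, ties fall back to column order.
Sex is excluded from the power-form screen — a power of a median is
meaningless for a binary covariate. `run_stepwise()` then alternates a full
forward phase (add the largest-drop extension while the drop exceeds 3.84,
the $\chi^2_1$ 5% quantile) and a full backward phase (remove the effect
whose deletion raises the OFV least while that rise is at most 6.64, the 1%
quantile), searching effects on $CL/F$, $V/F$, $V_2/F$ and $CL_2/F$. All
selection machinery accepts an injectable fitting function, which the test
suite exploits to verify the decision logic exactly against a linear-model
likelihood, separately from end-to-end FOCE runs.

## Diagnostics

The VPC and the NPDE consume one simulation harness
(`simulate_replicates()`): fresh etas and residuals at the observed design.
The VPC compares observed 5th/50th/95th percentiles per nominal-time bin
(the design is nominal-time sparse sampling, so bins are the nominal times,
on absolute time or time-after-dose) with 95% bands of the same percentiles
across replicates; it is uncorrected (no prediction correction), matching
how such studies display all arms together. The NPDE decorrelates each
subject's observed and simulated vectors with the simulated mean and
covariance (Cholesky), computes rank probabilities clipped to
$[1/2K, 1-1/2K]$, maps them through $\Phi^{-1}$, and reports a t-test of
mean zero, a $\chi^2$ test of variance one and a Shapiro-Wilk test.
CWRES follow the FOCE linearization: residuals around
$\hat f - J\eta^*$ decorrelated by the Cholesky factor of
$J\Omega J^\top + V$. The bootstrap resamples subjects with replacement
*stratified by dose arm* (arm sizes of 2-5 make unstratified resamples
degenerate; the flag is recorded in the output) and summarizes refits by
medians, RSE% and percentile CIs.

## NCA and dose proportionality

`nca_profile()` implements linear-up/log-down trapezoids, terminal slope by
best adjusted-$r^2$ log-linear regression over the last 3-6 points excluding
Tmax (flagging the extrapolation when fewer than 3 points or $r^2 < 0.8$),
and the standard derived quantities. Dose proportionality is the Pearson
correlation of arm-mean exposure against dose, reported to two decimals with
a log-log variant alongside, because independent recomputation from the
published arm means reproduces the printed 0.99 for both Cmax cells but
yields about 0.97 for the single-dose AUC cell (and about 0.99 for the
multiple-dose one) — the mirror image of the printed labels, most plausibly
a transposition. The packaged `orin_exposure_summary()` carries those
published means; only the two Cmax cells are treated as reproducible
anchors.

## Steady-state covariate impact

`simulate_covariate_effects()` draws 500 virtual patients per scenario
(covariates fixed at the published 5th/95th percentiles — LBW 30.11/59.98
kg, TBIL 5.22/22.24 umol/L — everything else at reference medians), computes
each patient's steady-state trough, peak and interval AUC analytically at
900 mg every 24 h, and reports the ratio of scenario mean to reference mean
with a bootstrap CI over virtual patients. The reference and every scenario
share the same random-effect draws (common random numbers): each virtual
patient is compared against their own counterfactual at the reference
covariates, which leaves the estimand untouched but removes most of the
Monte-Carlo variance of the ratio, making the reported fold changes
essentially seed-independent at $n = 500$. Whether the original simulation
included IIV is unstated; both paths exist (`iiv = FALSE` gives
deterministic typical-patient ratios, to which the IIV ratios converge as
$n$ grows), and the published fold changes are checked under the IIV path at
the stated $n = 500$. A fold change outside 80-125% is flagged clinically
significant. Residual error is excluded from exposure — it is assay noise,
not kinetics.

## The synthetic-trial generator

`generate_trial()` emulates the study design exactly: 25 subjects in arms of
3/3/4/3/3/5/4 at 100-900 mg; a dose at $t=0$ and daily doses from 96 h to
576 h; sampling at 0, 1, 2, 4, 6, 8, 12, 24, 48, 72, 96 h and 576 + (0, 1,
2, 4, 6, 8, 12, 24) h — 475 nominal samples; concentrations from the final
model with proportional error, truncated at zero; BLQ flagging below the
50 ng/mL assay LLOQ (BLQ records are kept but excluded from estimation — the
simplest defensible rule, as the original analysis does not state one); and
a dropout knob removing a uniform random fraction of observation records
(default 4/475, echoing the reported 471 without guessing why four samples
are missing). The day-21 pre-dose sample falls out of superposition as a
near-steady-state trough, not zero.

Covariates: sex (13:12), age, height and BMI are truncated normals; weight
is BMI times height squared (clamped to the observed 42-80 kg range); all
body-size covariates then flow through `derive_covariates()`, so derived
quantities always honor their formulas. Laboratory covariates are
independent truncated lognormals matched to the published median/IQR and
truncated to the published range. Height and BMI share a Gaussian copula
with correlation 0.7, and the height/BMI margins (male height N(171, 5.5),
female N(156, 5.5), BMI N(22.6, 4.2)) were calibrated once so that lean body
weight reproduces the published 5th/50th/95th percentiles (30.11, 45.13,
59.98 kg) — those percentiles drive the clinically relevant simulation
scenarios, so the generator treats them as the primary calibration targets
and the remaining marginals as plausibility checks. What the generator does
*not* emulate: correlated laboratory panels (a correlation matrix can be
supplied in principle, but the published table gives marginals only), assay
drift, re-analysis, enrollment dynamics, time-varying covariates, or
inter-occasion variability. Passing tests therefore demonstrate correctness
of the machinery under the stated statistical structure, not robustness to
real-data pathologies outside it.

## Problem sizes and reproducibility

The test suite establishes calibration claims at deliberately chosen sizes:
quadrature cross-checks on 4-subject toys; NPDE null calibration over 50
simulated datasets of 10 subjects with 250 replicates each; forward-selection
type-I rates over 25 datasets of 6 subjects under a no-IIV model (where the
OFV is exact weighted least squares); bootstrap coverage at 60 refits; and
the parameter-recovery experiment at the full published design (25 subjects,
471 records) over 5 replicate seeds. The exposure simulation uses the
study's own $n = 500$. `run_pipeline()` derives per-stage child seeds from
one global seed, so stages rerun independently and two same-seed runs are
byte-identical; every artifact directory carries a manifest with the seed,
configuration hash and package version.

## Known limitations

* FOCE here is FOCE-with-interaction, not the proprietary FOCE-ELS variant;
  absolute OFVs are not comparable across engines.
* The supplementary formulas for the covariate effects on $CL_2/F$, $V/F$
  and $V_2/F$ were not published; the package assumes the same power form
  with the published exponents and reference medians.
* One published confidence interval (CL/F, 0.95-11.77) is inconsistent with
  its 5.31% RSE and is almost certainly a misprint; the packaged fixture
  stores point estimates only.
* With 25 subjects and four IIV terms, some variance components are weakly
  identified; recovery tests target the well-identified typical values
  ($CL/F$, $V/F$), and fits report non-convergence rather than masking it.
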