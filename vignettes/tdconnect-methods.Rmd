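---
title: "Methods: from intertemporal choices to prefrontal effective connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from intertemporal choices to prefrontal effective connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdconnect)
```

# Overview

`tdconnect` implements a complete analysis chain for a monetary
intertemporal-choice fMRI study of 27 subjects: behavioral estimation of
hyperbolic discount rates, first-level GLMs with value modulators,
two-region dynamic causal modelling (DCM) between dorsolateral prefrontal
cortex (dlPFC-BA46, region *d*) and ventromedial prefrontal cortex (vmPFC,
region *v*), random-effects Bayesian model selection over a 64-model space,
Bayesian parameter averaging, and leave-one-subject-out elastic-net
prediction of discount rates from connectivity parameters. Because no
subject-level imaging data are distributed, the package ships a
synthetic-cohort generator that reproduces the study's design exactly
(the fixed 18-delay x 6-amount offer menu, 216 trials over two runs of 323
volumes at TR = 2.5 s) and drives all tests end to end.

# Behavioral model

Each trial offers $A (25--54 USD) after a delay of D days (7--200) against
a constant immediate $25. Subjective value follows hyperbolic discounting,

$$dSV = \frac{A}{1 + kD},$$

with a per-day discount rate $k \ge 0$, and the probability of accepting the
delayed option is the softmax

$$P(\text{yes}) = \bigl(1 + e^{b\,(25 - dSV)}\bigr)^{-1},$$

with slope $b \ge 0$. `fit_discounting()` maximizes the Bernoulli likelihood
of the responded choices in $(\log k, \log b)$ with box-constrained
quasi-Newton iterations from a 3 x 3 grid of starting points; the log
parameterization removes the positivity constraints, and the multi-start
guards against local optima. Missed trials (no button press within 3 s,
about 2% of trials) are excluded from the likelihood and from all GLM
modulators. $k$ is searched in $[10^{-6}, 1]$ per day: outside that range
the 7--200-day menu is uninformative, so wider bounds only add flat
directions. The $25 reference is a named argument throughout, not a
hard-coded constant.

Subjects accepting the delayed option on strictly more than half of their
responded trials form the wait group (WG); all others, including an exact
tie, the now group (NG). The tie goes to NG because the defining rule for
WG is a strict majority; the threshold is an argument for sensitivity
analyses. The relative value regressor is
$rdSV = dSV - 25$ for WG and $25 - dSV$ for NG, a reference-point recoding
relative to each subject's modal choice.

Degenerate data are flagged rather than rejected: all-accept or all-reject
runs drive $k$ to its bound, and data whose best fit does not improve on a
coin-flip likelihood by at least 2 log-units (e.g. generated with $b = 0$)
mark $k$ as unidentified. Both set `boundary = TRUE`.

# Synthetic cohort

`simulate_cohort()` draws, per subject,

* $\log k \sim \mathcal N(-4.5, 1.0)$ (per day). On this offer menu that
  spans mostly-wait to mostly-now behavior and reproduces a roughly 15/12
  WG/NG split, matching the study's composition;
* $\log b \sim \mathcal N(\log 0.5, 0.3)$, giving psychometric slopes steep
  enough that 216 trials identify $k$ well but with visible choice noise;
* choices from the softmax model itself, so the generator and the fitted
  model agree by construction; 2% of trials are marked missed;
* reaction times from a lognormal truncated to the 3 s window whose means
  reproduce the sign of the group-by-choice interaction (WG faster when
  accepting, NG faster when declining); magnitudes are qualitative only;
* trial onsets re-timed with the realized RTs (the offer screen terminates
  at the button press, followed by 250 ms feedback and a uniform 2--6 s
  fixation), which keeps every 108-trial run inside its 323 volumes.

Ground-truth DCM parameters are cohort means (Hz) plus between-subject
scatter (SD 0.05) and between-run scatter (SD 0.02). The later-choice
d-to-v modulation is planted as a linear function of the standardized
$-\log k$ with slope `effect_size` (default 0.25 Hz per SD) plus
$\mathcal N(0, 0.05)$ scatter; `effect_size = 0` produces null cohorts.
BOLD observation noise is AR(1) Gaussian ($\rho = 0.2$, marginal SD 0.35%
signal), chosen to give region-level signal-to-noise near 3 — generous but
within the range of averaged ROI time courses — and to exercise the GLM's
AR(1) step.

Ground truth is stored in a separate `ground_truth` slot that no estimation
function reads; the test suite verifies that removing it leaves every
estimate bit-identical. What passing tests show, and what they do not: the
generator realizes the fitted models' own assumptions (hyperbolic values,
softmax choices, bilinear dynamics, balloon observation). Success on these
cohorts demonstrates correctness and calibration of the estimation
machinery, not robustness to the model misspecification, physiological
noise, or motion artifacts present in real data.

# First-level GLM

Each run contributes three task regressors built on a 0.1 s microtime
grid, convolved with the canonical double-gamma HRF (peak near 5 s,
undershoot near 15 s, unit peak; no derivative terms since the synthetic
data contain no latency variation), and sampled at the TR grid:

1. a decision-screen indicator with duration equal to the trial's RT;
2. the indicator modulated by the value regressor (dSV or rdSV),
   mean-centered per run before convolution;
3. the indicator modulated by Accept (1 for delayed choices), orthogonalized
   against the convolved value column so shared variance is assigned to
   value.

Orthogonalization after convolution is one of two defensible conventions
(the alternative orthogonalizes the modulator vectors before convolution);
the sign-flip invariance that matters downstream — replacing dSV by rdSV
changes only signs, leaving |t| and model evidence untouched — holds under
both and is unit-tested. Nuisance columns are per-run intercepts, linear
trends, and a 128 s discrete-cosine high-pass basis; motion regressors are
accepted but the synthetic data have none.

`fit_glm()` estimates the lag-1 residual autocorrelation from an OLS pass,
prewhitens data and design per run, and refits. Model evidence is
approximated as the maximized Gaussian log-likelihood minus
$\tfrac{p}{2}\log n$ (Laplace/BIC). A full variational treatment would add
per-voxel shrinkage priors that matter at whole-brain scale but change
nothing in the two-ROI ranking here, and the approximation is invariant to
modulator sign and scale — exactly the property the full-versus-reduced
comparison needs. `compare_full_vs_reduced()` feeds the per-subject
evidence pairs into the same random-effects model selection used for the
DCM families.

# Dynamic causal model

Neural dynamics are bilinear over the two regions,

$$\dot z = \Bigl(A + \textstyle\sum_j u_j(t) B_j\Bigr) z + C u(t),$$

with conditions $j \in \{\text{all choices}, \text{later choices}\}$ as
modulatory inputs (boxcars of duration RT) and two driving inputs: the
trial-wise rdSV (scaled by the $25 reference so gains are order one) and
the Accept events. Self-connections are fixed at $-0.5\,e^{\theta}$ Hz with
$\theta = 0$, enforcing stability; condition-specific self-modulations are
estimated. Each region's observation runs through a balloon model
(vasodilatory signal, inflow, volume, deoxyhemoglobin) with literature
constants $\kappa = 0.64$, $\gamma = 0.32$, $\tau = 2$, $\alpha = 0.32$,
$E_0 = 0.4$, $V_0 = 0.04$; fixing rather than estimating the hemodynamics
keeps the 12-parameter inversion well conditioned at two regions, at the
cost of absorbing hemodynamic variability into coupling estimates.

Integration is fixed-step RK4 on a 0.1 s microtime grid (events shorter
than the TR are resolved on that grid and BOLD is sampled at the TR); a
pure-R reference integrator reproduces the compiled one to machine
precision in the test suite, and halving the step changes the output by
less than $10^{-4}$ RMS.

`dcm_invert()` is a variational-Laplace scheme: Gaussian priors (zero mean;
variance 1/16 on couplings and modulations, 1 on input gains), iterated
Gauss--Newton on the log-joint with step halving, per-region noise
precisions updated by maximum likelihood, and the free energy
$F = \text{accuracy} - \text{complexity}$ from the Laplace approximation at
the mode. Data and prediction are mean-centered per region, absorbing
baselines. Finite-difference Jacobians (step $10^{-3}$) are adequate
because the forward map is smooth in all 12 parameters.

# Model space and group statistics

The 64-model space crosses 4 families — defined by where the two driving
inputs enter: (1) rdSV to v and Accept to d, (2) both to v, (3) both to d,
(4) swapped — with 16 models per family from the on/off combinations of the
four between-region modulations (d-to-v and v-to-d, under the all-choices
and later-choices conditions). Baseline couplings and self-modulations are
present in every model, so each family contains exactly one full model.
Other within-family compositions are conceivable (switching all six
condition-by-connection pairs would give 64 per family); this reading —
switch only the between-region modulations, two conditions by two
directions — yields exactly 16 and keeps every model nested in the
family's full model. The
enumeration accepts a pluggable policy function so alternative readings
drop in without touching the rest of the pipeline.

`rfx_bms()` implements the hierarchical Dirichlet-multinomial model of
population model frequencies with variational updates; exceedance
probabilities come from $10^6$ seeded Dirichlet draws (Monte-Carlo error
about $10^{-3}$). Family comparison marginalizes each subject's evidence
over the family under a uniform within-family prior (log-mean-exp) before
the random-effects step; this makes the family comparison exactly invariant
to duplicating a model within a family, which a model-level Dirichlet with
rescaled priors does not achieve. `bpa()` pools subject posteriors by
precision weighting with the shared prior removed $n-1$ times — the closed
form of the joint Gaussian product — and `connectivity_tests()` reports
one-sample t-tests and BPA posterior probabilities side by side.

# Prediction

`extract_features()` runs the estimation-only path (fit discounting, recode
rdSV, invert the family-1 full model per run) and assembles the 12
posterior means per run as features; hemodynamic constants are fixed and
therefore excluded. `loo_predict()` holds out one subject at a time, fits
an elastic net (mixing $\alpha = 0.3$, the study's setting; the penalty
level is chosen by seeded 5-fold cross-validation
inside each training fold over a 20-point log-spaced path, configurable to
a fixed value), and classifies the held-out subject's fitted $\log k$
against the training-set mean. The classification threshold is on the log
scale, matching the regression target; standardization, penalty selection
and the threshold use training data only. Balanced accuracy
$\tfrac12(\text{sensitivity} + \text{specificity})$ summarizes the
confusion matrix, with a 95% interval from independent Beta posteriors on
sensitivity and specificity averaged by seeded Monte-Carlo, and the
Spearman correlation of predicted versus fitted $\log k$ covers the
continuous ranking. The coordinate-descent solver is validated against
closed-form OLS and soft-thresholding solutions, a projected-gradient
reference, and glmnet.

Ablations drop feature groups from the regression only — parameters are
never re-estimated — with the region-local groups read as
{value input gain, all-choices self, later-choices self} for vmPFC and
{Accept input gain, all-choices self, later-choices self} for dlPFC,
following the full model's parameter grouping. `specificity_swap()`
replaces the dlPFC series (with matched-variance noise, a copy control, or
user-supplied series) and re-runs inversion and prediction. A meaningful
swap test needs a cohort whose discounting signal lives only in the dlPFC
series — in the default planted cohort the d-to-v modulation is expressed
in the vmPFC series and survives the swap —
so `simulate_dlpfc_effect_cohort()` silences the d-to-v transfer in the
ground truth and plants the effect in the Accept input gain to dlPFC;
swapping that region then collapses an otherwise strong prediction to
chance.

# Numerical choices and problem sizes

* Offer-grid validation is strict: 18 rows, 6 nondecreasing amounts each,
  strictly increasing delays, integers only.
* The discounting likelihood is computed on the log scale, so extreme
  slopes cannot underflow.
* Gauss--Newton falls back to a pseudo-inverse if the regularized Hessian
  is numerically singular, and flags non-convergence instead of erroring.
* Exceedance draws, cross-validation folds, interval draws and every other
  stochastic step take derived seeds, so identical configurations produce
  byte-identical reports (JSON serialized at 12 significant digits).
* The test suite exercises the full chain at the study's design values with
  desk-scale replication counts: 50 subjects for behavioral recovery, 50
  noisy runs for posterior coverage, one 27-subject cohort across the four
  family-full models for family selection, 50 planted and 12 null
  27-subject single-run cohorts for the prediction analog, ablations on 12
  of the planted cohorts, and 3 region-swap cohorts. The four family-full
  models stand in for the 64-model space in group selection runs; the full
  space is enumerated and can be inverted through `run_pipeline()` when
  hours of compute are acceptable.

# Known limitations

* The synthetic cohort cannot certify behavior on real fMRI data (no
  misspecification, motion, or physiological noise; see above).
* Hemodynamic parameters are fixed, not estimated; systematic hemodynamic
  differences between regions would bias coupling estimates.
* The evidence approximation for GLMs is BIC-like; absolute evidence values
  are not comparable across packages, only differences within a model pair.
* With a single run and moderate noise, weakly identified DCM parameters
  shrink toward the prior mean differentially across subjects whose event
  streams differ, so even null-cohort features retain faint behavioral
  signatures; the prediction null distribution is centered on chance but
  has substantial seed-to-seed spread.
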