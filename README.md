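# tdconnect

Links individual differences in temporal discounting to directed
(effective) connectivity between dorsolateral prefrontal cortex
(dlPFC-BA46) and ventromedial prefrontal cortex (vmPFC) during
intertemporal monetary choice. The package is for computational
neuroscientists who want a fully testable, end-to-end implementation of
this analysis chain — behavior to GLM to dynamic causal modelling to
out-of-sample prediction — without access to subject-level imaging data.

## What it computes

Subjects choose between $25 now and $A in D days (a fixed 18-delay x
6-amount menu, 216 trials over two fMRI runs of 323 volumes, TR = 2.5 s).
The analysis chain is:

1. **Discounting behavior.** Hyperbolic values `dSV = A / (1 + kD)` and
   softmax choices `P(yes) = 1 / (1 + exp(b (25 − dSV)))`; `(k, b)` fit by
   maximum likelihood per subject. Subjects split into wait/now groups by
   modal choice, defining the relative value signal `rdSV = ±(dSV − 25)`.
2. **First-level GLM.** Decision-screen regressors with dSV/rdSV and
   Accept modulators (Accept orthogonalized against value), canonical HRF,
   128 s high-pass, AR(1) prewhitening; group one-sample t-tests and a
   full-vs-reduced evidence comparison for the value regressor.
3. **Two-region DCM.** Bilinear neural dynamics
   `dz/dt = (A + Σ u_j B_j) z + C u` with a balloon hemodynamic
   observation model, inverted by variational Laplace; 64 models in 4
   families (by driving-input placement) compared with random-effects
   Bayesian model selection and exceedance probabilities; group parameters
   by Bayesian parameter averaging.
4. **Prediction.** Leave-one-subject-out elastic net (alpha = 0.3) from the
   12 DCM parameters per run to log k, scored by balanced accuracy
   `(TP/(TP+FN) + TN/(TN+FP)) / 2` with a Beta-posterior interval, plus
   ablation and region-swap specificity tests.

A synthetic-cohort generator (`simulate_cohort()`) reproduces the study
design with known ground truth, so every stage is exercised and validated
in code.

## Worked example

```r
library(tdconnect)

co  <- simulate_cohort(cohort_config(seed = 101, runs_per_subject = 1L))
ft  <- extract_features(co)          # fits behavior, inverts the DCM per run
pr  <- loo_predict(ft, seed = 5)     # leave-one-subject-out elastic net
pr
#> prediction_result: MBA = 0.808 (95% interval 0.611-0.897), rho = 0.770 (p = 5.49e-06)
#>   confusion: TP=9 FN=3 TN=13 FP=2

abl <- ablation_suite(ft, seed = 5)
sapply(abl, function(a) round(a$balanced_accuracy, 3))
#> vmpfc_local dlpfc_local      d_to_v      v_to_d
#>       0.850       0.808       0.492       0.892
```

Reading the numbers: on this synthetic cohort the connectivity features
classify held-out subjects as above/below the median discount rate with
81% balanced accuracy and rank-correlate with fitted log k at rho = 0.77.
Dropping the dlPFC-to-vmPFC coupling columns (`d_to_v`) collapses accuracy
to chance (0.49) while dropping the opposite direction does not — the
planted ground-truth effect lives in the d-to-v later-choice modulation,
and the pipeline finds it.

The full pipeline (cohort on disk, GLM reports, family-level model
selection, prediction with ablations) runs with:

```r
cfg <- pipeline_config(seed = 7)
run_pipeline(cfg, "out/")            # writes one JSON report per stage
```

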