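Package: tdconnect
Title: Temporal Discounting and Prefrontal Effective Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline linking intertemporal choice
    behavior to effective connectivity between dorsolateral and ventromedial
    prefrontal cortex. Provides maximum-likelihood estimation of hyperbolic
    discount rates from binary accept/reject choices, first-level fMRI
    general linear models with parametric value modulators and AR(1)
    prewhitening, a two-region bilinear dynamic causal model with a balloon
    hemodynamic observation model and variational-Laplace inversion,
    random-effects Bayesian model selection with exceedance probabilities,
    Bayesian parameter averaging, and leave-one-subject-out elastic-net
    prediction of discount rates from connectivity parameters scored by
    balanced accuracy. A synthetic-cohort generator reproduces the study
    design (27 subjects, 2 runs of 323 volumes at TR = 2.5 s, a fixed
    18 x 6 offer grid) so every stage is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmnet
Config/testthat/edition: 3
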