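#' Enumerate the 64-model, 4-family DCM space
#'
#' Four families by driving-input placement (see [dcm_spec()]); within each
#' family, 16 models from the on/off combinations of the four between-region
#' modulatory connections (d->v and v->d, each under the all-choices and
#' later-choices conditions). Baseline couplings and self-modulations are
#' present in every model, so each family contains exactly one full model
#' (all four switches on). The within-family composition is a pluggable
#' policy: supply `policy` to enumerate a different switch set.
#'
#' @param policy Function returning a data frame of logical switch columns
#'   `all.d_to_v`, `all.v_to_d`, `later.d_to_v`, `later.v_to_d`, one row per
#'   within-family model. Default: all 16 combinations.
#' @return List of class `model_space`: `specs` (list of `dcm_spec`),
#'   `family` (integer vector), `index` (within-family index), `full_model`
#'   (indices of the four full models).
#' @export
enumerate_models <- function(policy = default_modulation_policy) {
  combos <- policy()
  need <- c("all.d_to_v", "all.v_to_d", "later.d_to_v", "later.v_to_d")
  stopifnot(all(need %in% names(combos)))
  specs <- list(); fam <- integer(0); idx <- integer(0)
  for (f in 1:4) {
    for (i in seq_len(nrow(combos))) {
      sw <- unlist(combos[i, need])
      specs[[length(specs) + 1L]] <- dcm_spec(family = f, mod_on = sw)
      fam <- c(fam, f); idx <- c(idx, i)
    }
  }
  full <- which(vapply(specs, function(s) all(s$mod_on), logical(1)))
  structure(list(specs = specs, family = fam, index = idx,
                 full_model = full),
            class = "model_space")
}

#' @rdname enumerate_models
#' @export
default_modulation_policy <- function() {
  expand.grid(all.d_to_v = c(FALSE, TRUE), all.v_to_d = c(FALSE, TRUE),
              later.d_to_v = c(FALSE, TRUE), later.v_to_d = c(FALSE, TRUE))
}

# Dirichlet sampler via gamma draws.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), n, k)
  x / rowSums(x)
}

#' Random-effects Bayesian model selection
#'
#' Fits the hierarchical Dirichlet-multinomial model of model frequencies in
#' the population by variational updates (Stephan et al. 2009): subject-wise
#' posterior model assignments and a Dirichlet posterior over frequencies.
#' Exceedance probabilities — the belief that each model is more frequent
#' than every other — are estimated by seeded Monte-Carlo draws from the
#' fitted Dirichlet.
#'
#' @param log_evidence Matrix (subjects x models) of log model evidences.
#' @param alpha0 Prior Dirichlet concentrations (default 1 per model).
#' @param seed Seed for the exceedance draws.
#' @param n_draws Number of Dirichlet draws (default 1e6).
#' @param max_iter,tol Variational iteration controls.
#' @return List of class `bms_result`: `alpha` (posterior concentrations),
#'   `expected_prob`, `exceedance`, `assignment` (subjects x models posterior
#'   weights).
#' @export
rfx_bms <- function(log_evidence, alpha0 = NULL, seed = 1L, n_draws = 1e6,
                    max_iter = 200L, tol = 1e-8) {
  log_evidence <- as.matrix(log_evidence)
  if (any(!is.finite(log_evidence))) stop("log evidences must be finite")
  k <- ncol(log_evidence)
  if (k < 2L) stop("need at least 2 models to compare")
  if (is.null(alpha0)) alpha0 <- rep(1, k)
  alpha <- alpha0
  for (it in seq_len(max_iter)) {
    lg <- sweep(log_evidence, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    lg <- lg - apply(lg, 1, max)
    g <- exp(lg) / rowSums(exp(lg))
    alpha_new <- alpha0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol) { alpha <- alpha_new; break }
    alpha <- alpha_new
  }
  xp <- exceedance_from_dirichlet(alpha, seed = seed, n_draws = n_draws)
  structure(list(alpha = alpha,
                 expected_prob = alpha / sum(alpha),
                 exceedance = xp,
                 assignment = g),
            class = "bms_result")
}

exceedance_from_dirichlet <- function(alpha, seed = 1L, n_draws = 1e6,
                                      group = NULL, chunk = 1e5) {
  rng <- local_rng(seed)
  k <- if (is.null(group)) length(alpha) else length(unique(group))
  counts <- numeric(k)
  done <- 0
  while (done < n_draws) {
    m <- min(chunk, n_draws - done)
    r <- rdirichlet(m, alpha)
    if (!is.null(group)) {
      r <- t(rowsum(t(r), group))
    }
    counts <- counts + tabulate(max.col(r, ties.method = "random"), nbins = k)
    done <- done + m
  }
  restore_rng(rng)
  counts / n_draws
}

#' Family-level Bayesian model selection
#'
#' Marginalizes each subject's evidence over the models of a family under a
#' uniform within-family prior (log-mean-exp of the member evidences), then
#' runs the random-effects BMS over the resulting family evidences. With this
#' partitioning, family comparisons are exactly invariant to duplicating a
#' model inside a family, and unequal family sizes carry no advantage.
#'
#' @param log_evidence Matrix (subjects x models) of log evidences.
#' @param family Integer/factor vector assigning each model to a family.
#' @param seed,n_draws Monte-Carlo controls for the exceedance estimate.
#' @return List of class `family_bms_result`: `exceedance` (per family),
#'   `expected_prob`, `alpha`, `families`, `family_evidence`.
#' @export
family_bms <- function(log_evidence, family, seed = 1L, n_draws = 1e6) {
  log_evidence <- as.matrix(log_evidence)
  if (length(family) != ncol(log_evidence))
    stop("one family label per model required")
  fams <- sort(unique(family))
  if (length(fams) < 2L) stop("need at least 2 families")
  fam_ev <- sapply(fams, function(f) {
    lE <- log_evidence[, family == f, drop = FALSE]
    m <- apply(lE, 1, max)
    m + log(rowMeans(exp(lE - m)))        # log-mean-exp per subject
  })
  if (is.null(dim(fam_ev))) fam_ev <- matrix(fam_ev, nrow = 1)
  fit <- rfx_bms(fam_ev, seed = seed, n_draws = n_draws)
  structure(list(exceedance = stats::setNames(fit$exceedance,
                                              paste0("family", fams)),
                 expected_prob = stats::setNames(fit$expected_prob,
                                                 paste0("family", fams)),
                 alpha = fit$alpha, families = fams,
                 family_evidence = fam_ev),
            class = "family_bms_result")
}

#' Bayesian parameter averaging over subjects
#'
#' Precision-weighted pooling of Gaussian subject posteriors that share one
#' prior: the group precision is the sum of subject precisions minus (n-1)
#' times the prior precision (removing the prior counted n times), and the
#' group mean weights each subject mean by its precision with the matching
#' prior correction. Equivalent to the Gaussian posterior from the pooled
#' likelihood under the shared prior.
#'
#' @param posteriors List of `dcm_posterior` objects (or lists with `mean`
#'   and `cov`) sharing one parameterization.
#' @param prior_mean,prior_cov Shared prior (defaults taken from the first
#'   posterior's `spec`).
#' @return List of class `bpa_result`: `mean`, `cov`, `prob_positive`, `n`.
#' @export
bpa <- function(posteriors, prior_mean = NULL, prior_cov = NULL) {
  if (!length(posteriors)) stop("need at least one posterior")
  nm <- names(posteriors[[1]]$mean)
  for (p in posteriors)
    if (!identical(names(p$mean), nm))
      stop("posteriors do not share a parameterization")
  if (is.null(prior_mean)) prior_mean <- posteriors[[1]]$spec$prior_mean
  if (is.null(prior_cov)) prior_cov <- diag(posteriors[[1]]$spec$prior_var,
                                            length(nm))
  n <- length(posteriors)
  P0 <- solve(prior_cov)
  prec <- Reduce(`+`, lapply(posteriors, function(p) solve(p$cov))) -
    (n - 1) * P0
  wmean <- Reduce(`+`, lapply(posteriors, function(p) solve(p$cov, p$mean))) -
    (n - 1) * as.numeric(P0 %*% prior_mean)
  cov_g <- solve(prec)
  cov_g <- (cov_g + t(cov_g)) / 2
  mean_g <- stats::setNames(as.numeric(cov_g %*% wmean), nm)
  sdv <- sqrt(pmax(diag(cov_g), 1e-300))
  structure(list(mean = mean_g, cov = cov_g,
                 prob_positive = stats::setNames(
                   1 - stats::pnorm(0, mean_g, sdv), nm),
                 n = n),
            class = "bpa_result")
}

#' Group tests of the connectivity parameters
#'
#' Side-by-side frequentist and Bayesian summaries for each coupling
#' parameter across subjects: a two-tailed one-sample t-test on the posterior
#' means, and the BPA posterior probability that the parameter exceeds zero.
#'
#' @param posteriors List of subject `dcm_posterior` objects (same spec).
#' @return Data frame with one row per parameter: `parameter`, `mean`, `t`,
#'   `p`, `bpa_mean`, `bpa_prob_positive`.
#' @export
connectivity_tests <- function(posteriors) {
  if (length(posteriors) < 3L) stop("need at least 3 subjects")
  nm <- names(posteriors[[1]]$mean)
  M <- t(vapply(posteriors, function(p) p$mean, numeric(length(nm))))
  avg <- bpa(posteriors)
  rows <- lapply(seq_along(nm), function(j) {
    gt <- group_ttest(M[, j])
    data.frame(parameter = nm[j], mean = mean(M[, j]),
               t = gt$t, p = gt$p,
               bpa_mean = avg$mean[j],
               bpa_prob_positive = avg$prob_positive[j],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
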