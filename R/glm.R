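#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities with the standard shape parameters
#' (response peak near 5 s, undershoot near 15 s, undershoot ratio 1/6),
#' normalized to unit peak, supported on \[0, 32\] s.
#'
#' @param time_grid Times in seconds at which to evaluate the kernel.
#' @param peak_shape,peak_rate Gamma parameters of the positive lobe.
#' @param under_shape,under_rate Gamma parameters of the undershoot.
#' @param undershoot_ratio Weight of the undershoot lobe.
#' @return Numeric vector of kernel values; 0 outside \[0, 32\] s.
#' @export
hrf <- function(time_grid, peak_shape = 6, peak_rate = 1,
                under_shape = 16, under_rate = 1, undershoot_ratio = 1 / 6) {
  h <- stats::dgamma(time_grid, shape = peak_shape, rate = peak_rate) -
    undershoot_ratio * stats::dgamma(time_grid, shape = under_shape, rate = under_rate)
  h[time_grid < 0 | time_grid > 32] <- 0
  # unit peak on a fine internal grid so normalization is grid-independent
  fine <- seq(0, 32, by = 0.01)
  pk <- max(stats::dgamma(fine, peak_shape, peak_rate) -
              undershoot_ratio * stats::dgamma(fine, under_shape, under_rate))
  h / pk
}

# Discrete cosine high-pass basis (cutoff in seconds), constant excluded.
dct_highpass_basis <- function(n, tr, cutoff = 128) {
  k_max <- floor(2 * n * tr / cutoff)
  if (k_max < 1L) return(matrix(numeric(0), n, 0))
  t_idx <- seq_len(n) - 1L
  sapply(seq_len(k_max), function(r) cos(pi * (2 * t_idx + 1) * r / (2 * n)))
}

# Boxcar (possibly amplitude-scaled) event stream on a microtime grid.
microtime_stream <- function(onsets, durations, amplitudes, n_micro, dt) {
  u <- numeric(n_micro)
  for (i in seq_along(onsets)) {
    a <- floor(onsets[i] / dt) + 1L
    b <- min(n_micro, floor((onsets[i] + max(durations[i], dt)) / dt))
    if (a <= n_micro && b >= a) u[a:b] <- u[a:b] + amplitudes[i]
  }
  u
}

convolve_downsample <- function(u, dt, sample_idx) {
  kern <- hrf(seq(0, 32, by = dt))
  conv <- stats::convolve(u, rev(kern), type = "open")[seq_along(u)] * dt
  conv[sample_idx]
}

#' Build a first-level design matrix with parametric value modulators
#'
#' Constructs, per run, an indicator regressor for the decision screen
#' (duration = reaction time), a value-modulated copy (dSV or rdSV,
#' mean-centered per run before convolution), and an Accept-modulated copy
#' orthogonalized against the value column after convolution so that shared
#' variance is assigned to value. Events are laid out on a 0.1 s microtime
#' grid, convolved with the canonical HRF, and sampled at the TR grid.
#' Nuisance columns: per-run intercepts, linear trends, and a discrete
#' cosine high-pass basis (128 s cutoff by default).
#'
#' @param events Trial data frame (columns `onset`, `rt`, `choice`, `run`)
#'   covering one or more runs; missed trials are excluded.
#' @param values Per-trial value modulator (dSV or rdSV), aligned with
#'   `events` rows.
#' @param volumes Volumes per run.
#' @param tr Repetition time in seconds.
#' @param dt Microtime resolution in seconds.
#' @param hp_cutoff High-pass cutoff in seconds (NULL disables).
#' @param nuisance Optional extra nuisance matrix (e.g. head motion),
#'   `sum(volumes per run)` rows.
#' @return List of class `design_matrix`: `X` (rows = total volumes),
#'   `task_cols` (names of the condition/value/accept columns), `tr`,
#'   `frame_times`.
#' @export
build_design <- function(events, values, volumes, tr, dt = 0.1,
                         hp_cutoff = 128, nuisance = NULL) {
  stopifnot(length(values) == nrow(events))
  runs <- sort(unique(events$run))
  task <- NULL; nuis_blocks <- list()
  for (r in runs) {
    sel <- events$run == r & !is.na(events$choice) & events$choice != "missed"
    ev <- events[sel, , drop = FALSE]
    val <- values[sel]
    if (any(ev$onset + ev$rt > volumes * tr))
      stop("events extend beyond run duration")
    n_micro <- ceiling(volumes * tr / dt)
    sample_idx <- pmin(n_micro, floor(((seq_len(volumes) - 1L) * tr) / dt) + 1L)
    acc <- as.numeric(ev$choice == "accept")
    cond_u <- microtime_stream(ev$onset, ev$rt, rep(1, nrow(ev)), n_micro, dt)
    val_u  <- microtime_stream(ev$onset, ev$rt, val - mean(val), n_micro, dt)
    acc_u  <- microtime_stream(ev$onset, ev$rt, acc - mean(acc), n_micro, dt)
    cond <- convolve_downsample(cond_u, dt, sample_idx)
    valc <- convolve_downsample(val_u, dt, sample_idx)
    accc <- convolve_downsample(acc_u, dt, sample_idx)
    # assign shared variance to the value regressor
    if (sum(valc^2) > 0)
      accc <- accc - valc * sum(accc * valc) / sum(valc^2)
    task <- rbind(task, cbind(cond = cond, value = valc, accept = accc))
    blk <- cbind(intercept = rep(1, volumes),
                 trend = seq_len(volumes) - (volumes + 1) / 2)
    if (!is.null(hp_cutoff)) {
      dct <- dct_highpass_basis(volumes, tr, hp_cutoff)
      if (ncol(dct)) colnames(dct) <- paste0("dct", seq_len(ncol(dct)))
      blk <- cbind(blk, dct)
    }
    colnames(blk) <- paste0("run", r, "_", colnames(blk))
    nuis_blocks[[as.character(r)]] <- blk
  }
  if (!length(nuis_blocks)) stop("no runs found in events")
  n_rows <- vapply(nuis_blocks, nrow, integer(1))
  n_cols <- vapply(nuis_blocks, ncol, integer(1))
  nuis <- matrix(0, sum(n_rows), sum(n_cols))
  colnames(nuis) <- unlist(lapply(nuis_blocks, colnames))
  ro <- 0L; co <- 0L
  for (b in nuis_blocks) {
    nuis[ro + seq_len(nrow(b)), co + seq_len(ncol(b))] <- b
    ro <- ro + nrow(b); co <- co + ncol(b)
  }
  X <- cbind(task, nuis)
  if (!is.null(nuisance)) {
    stopifnot(nrow(nuisance) == nrow(X))
    X <- cbind(X, nuisance)
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop("design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  structure(list(X = X, task_cols = c("cond", "value", "accept"), tr = tr,
                 frame_times = (seq_len(nrow(X)) - 1L) * tr,
                 runs = rep(runs, each = volumes)),
            class = "design_matrix")
}

#' Fit a prewhitened GLM to one region's BOLD series
#'
#' Ordinary least squares residuals provide a pooled lag-1 autocorrelation
#' estimate; data and design are then AR(1)-prewhitened per run and refit by
#' generalized least squares. Contrast t-values are reported for the value
#' and Accept columns, and an approximate log model evidence (Laplace/BIC:
#' maximized Gaussian log-likelihood minus `p/2 * log(n)`) is recorded for
#' model comparison.
#'
#' @param series Numeric BOLD vector, length `nrow(design$X)`.
#' @param design A `design_matrix`.
#' @param contrasts Character vector of column names to test (default the
#'   value and accept task columns present in the design).
#' @return List of class `glm_result`: `beta`, `sigma2`, `rho`, `contrasts`
#'   (estimate, se, t, p per contrast), `log_evidence`, `df`.
#' @export
fit_glm <- function(series, design, contrasts = NULL) {
  X <- design$X
  if (length(series) != nrow(X)) stop("series length must equal design rows")
  if (any(!is.finite(series))) stop("non-finite values in series")
  if (is.null(contrasts))
    contrasts <- intersect(c("value", "accept"), colnames(X))
  ols <- stats::lm.fit(X, series)
  r <- ols$residuals
  runs <- design$runs
  num <- 0; den <- 0
  for (rr in unique(runs)) {
    ri <- r[runs == rr]
    num <- num + sum(ri[-1] * ri[-length(ri)])
    den <- den + sum(ri^2)
  }
  # first-order bias correction: OLS residual autocorrelation is biased by
  # about -p/n through the hat-matrix projection
  rho <- num / den + ncol(X) / length(series)
  rho <- max(min(rho, 0.95), -0.95)
  # whiten only when the autocorrelation is distinguishable from zero;
  # whitening with a noise-dominated estimate inflates the test size
  if (abs(rho) < 2 / sqrt(length(series))) rho <- 0
  W <- function(v) {
    out <- v
    for (rr in unique(runs)) {
      idx <- which(runs == rr)
      vi <- v[idx]
      out[idx] <- c(sqrt(1 - rho^2) * vi[1], vi[-1] - rho * vi[-length(vi)])
    }
    out
  }
  Xw <- apply(X, 2, W)
  yw <- W(series)
  fit <- stats::lm.fit(Xw, yw)
  n <- length(yw); p <- ncol(X)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / (n - p)
  xtxi <- chol2inv(chol(crossprod(Xw)))
  ct <- lapply(contrasts, function(cn) {
    j <- match(cn, colnames(X))
    est <- fit$coefficients[j]
    se <- sqrt(sigma2 * xtxi[j, j])
    tval <- est / se
    list(name = cn, estimate = unname(est), se = se, t = unname(tval),
         p = 2 * stats::pt(-abs(tval), df = n - p))
  })
  names(ct) <- contrasts
  sigma2_ml <- rss / n
  loglik <- -0.5 * n * (log(2 * pi * sigma2_ml) + 1)
  structure(list(beta = fit$coefficients, sigma2 = sigma2, rho = rho,
                 contrasts = ct,
                 log_evidence = loglik - 0.5 * p * log(n),
                 df = n - p),
            class = "glm_result")
}

#' One-sample group t-test on subject-level contrast estimates
#'
#' @param values Per-subject contrast values (length >= 3).
#' @return List `t`, `p`, `df`, `mean`, and `infinite` flag (TRUE when all
#'   values are identical and nonzero).
#' @export
group_ttest <- function(values) {
  if (length(values) < 3L) stop("need at least 3 subjects")
  s <- stats::sd(values)
  if (s == 0) {
    if (mean(values) == 0) stop("zero variance and zero mean: t undefined")
    return(list(t = sign(mean(values)) * Inf, p = 0,
                df = length(values) - 1L, mean = mean(values),
                infinite = TRUE))
  }
  tt <- stats::t.test(values, mu = 0)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean = mean(values), infinite = FALSE)
}

#' Compare the full value GLM against a reduced GLM without the value regressor
#'
#' For each subject, both models are fit to the region series: the full model
#' with condition + value + Accept columns and a reduced model that drops the
#' value column (all other regressors retained). Their approximate log
#' evidences feed a random-effects Bayesian model selection
#' ([rfx_bms()]), yielding the exceedance probability that the full model is
#' the more frequent explanation across subjects — a sign-independent test of
#' the value regressor's contribution.
#'
#' @param series_list List of per-subject BOLD vectors.
#' @param design_list List of per-subject full `design_matrix` objects.
#' @param seed Seed for the exceedance Monte-Carlo draws.
#' @param n_draws Dirichlet draws for exceedance estimation.
#' @return List: `evidence` (subjects x 2 matrix, columns full/reduced),
#'   `bms` ([rfx_bms()] result), `exceedance_full`.
#' @export
compare_full_vs_reduced <- function(series_list, design_list, seed = 1L,
                                    n_draws = 1e5) {
  stopifnot(length(series_list) == length(design_list))
  ev <- t(vapply(seq_along(series_list), function(i) {
    d <- design_list[[i]]
    full <- fit_glm(series_list[[i]], d)
    red <- d
    keep <- colnames(d$X) != "value"
    red$X <- d$X[, keep, drop = FALSE]
    reduced <- fit_glm(series_list[[i]], red, contrasts = "accept")
    c(full = full$log_evidence, reduced = reduced$log_evidence)
  }, numeric(2)))
  bms <- rfx_bms(ev, seed = seed, n_draws = n_draws)
  list(evidence = ev, bms = bms,
       exceedance_full = unname(bms$exceedance[1]))
}
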