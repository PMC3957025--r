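#' Configuration for a synthetic intertemporal-choice cohort
#'
#' Defaults reproduce the study design: 27 subjects, two runs of the choice
#' task with 323 volumes each at TR = 2.5 s, 216 trials per subject on the
#' packaged offer grid, ~2% missed responses. Discount rates are drawn as
#' log k ~ Normal(-4.5, 1) per day, spanning mostly-wait to mostly-now
#' behavior on this offer set; softmax slopes as log b ~ Normal(log 0.5,
#' 0.3). BOLD observation noise is AR(1) (rho 0.2) Gaussian. The ground-truth
#' dlPFC->vmPFC later-choice modulation is linked to -log k with slope
#' `effect_size` (Hz per SD of -log k) plus Normal(0, `effect_noise_sd`)
#' scatter; `effect_size = 0` gives a null cohort.
#'
#' @param n_subjects,runs_per_subject,volumes_per_run,tr_seconds Study shape.
#' @param logk_mean,logk_sd,logb_mean,logb_sd Behavioral parameter
#'   distributions (log scale).
#' @param rt_sdlog Log-scale SD of the truncated lognormal RT generator.
#' @param miss_rate Probability a trial is missed.
#' @param bold_noise_sd Marginal SD of the AR(1) BOLD noise (percent signal).
#' @param bold_ar1 Lag-1 autocorrelation of the BOLD noise.
#' @param effect_size Hz of later-choice d->v modulation per SD of -log k.
#' @param effect_noise_sd SD of subject scatter around the planted line.
#' @param later_dv_base Cohort-mean later-choice d->v modulation (Hz).
#' @param theta_jitter_sd,run_jitter_sd Between-subject / between-run scatter
#'   of the non-planted ground-truth DCM parameters.
#' @param dt Microtime integration step (s).
#' @param seed Integer seed (required).
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 27L, runs_per_subject = 2L,
                          volumes_per_run = 323L, tr_seconds = 2.5,
                          logk_mean = -4.5, logk_sd = 1.0,
                          logb_mean = log(0.5), logb_sd = 0.3,
                          rt_sdlog = 0.2, miss_rate = 0.02,
                          bold_noise_sd = 0.35, bold_ar1 = 0.2,
                          effect_size = 0.25, effect_noise_sd = 0.05,
                          later_dv_base = 0.15,
                          theta_jitter_sd = 0.05, run_jitter_sd = 0.02,
                          dt = 0.1, seed) {
  if (missing(seed)) stop("a seed is required for reproducibility")
  cfg <- as.list(environment())
  stopifnot(n_subjects > 0, runs_per_subject > 0, volumes_per_run > 0,
            tr_seconds > 0, dt > 0, miss_rate >= 0, miss_rate < 1,
            effect_size >= 0)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "cohort_config")
}

# Cohort-mean ground-truth DCM parameters (family-1 full model, Hz).
ground_truth_means <- function() {
  c(fixed.v_to_d = 0.05, fixed.d_to_v = 0.05,
    all.v_to_d = 0.05, all.v_self = -0.10, all.d_to_v = 0.25,
    all.d_self = -0.10,
    later.v_to_d = 0.00, later.v_self = 0.05, later.d_to_v = 0.15,
    later.d_self = 0.05,
    drive.value_to_v = 0.40, drive.accept_to_d = 0.50)
}

# Truncated lognormal RT draw, upper-bounded by the 3 s response window.
draw_rt <- function(n, mean_rt, sdlog, lower = 0.3, upper = 3) {
  meanlog <- log(mean_rt) - sdlog^2 / 2
  out <- stats::rlnorm(n, meanlog, sdlog)
  bad <- out < lower | out > upper
  while (any(bad)) {
    out[bad] <- stats::rlnorm(sum(bad), meanlog, sdlog)
    bad <- out < lower | out > upper
  }
  out
}

#' Simulate one subject's choice behavior
#'
#' Builds a 216-trial two-run session on the offer grid, draws accept/reject
#' choices from the softmax model at the subject's (k, b), marks missed
#' trials, draws reaction times from a truncated lognormal whose mean
#' reproduces the sign of the group-by-choice interaction (wait-group
#' subjects respond faster when accepting, now-group subjects faster when
#' rejecting), and re-times trial onsets using the realized RTs (the offer
#' screen terminates at the button press; feedback 250 ms).
#'
#' @param config A `cohort_config`.
#' @param subject_index Subject number (drives the derived seed).
#' @param k,b Optional fixed behavioral parameters; drawn from the config
#'   distributions when omitted.
#' @param grid Offer grid (defaults to the packaged grid).
#' @return List: `trials` (realized event table), `group`, `k`, `b`.
#' @export
simulate_subject_behavior <- function(config, subject_index, k = NULL,
                                      b = NULL, grid = load_offer_grid()) {
  seed_i <- derive_seed(config$seed, "behavior", subject_index)
  rng <- local_rng(seed_i)
  on.exit(restore_rng(rng))
  if (is.null(k)) k <- exp(stats::rnorm(1, config$logk_mean, config$logk_sd))
  if (is.null(b)) b <- exp(stats::rnorm(1, config$logb_mean, config$logb_sd))
  trials <- build_session(grid, derive_seed(seed_i, "session"))
  p <- p_accept(discounted_value(trials$amount, trials$delay, k), b)
  accept <- stats::runif(nrow(trials)) < p
  missed <- stats::runif(nrow(trials)) < config$miss_rate
  trials$choice <- ifelse(missed, "missed",
                          ifelse(accept, "accept", "reject"))
  resp <- trials$choice != "missed"
  group <- assign_group(trials)
  mean_rt <- matrix(c(1.13, 1.28,    # WG: accept, reject
                      1.28, 1.14),   # NG: accept, reject
                    2, 2, byrow = TRUE,
                    dimnames = list(c("WG", "NG"), c("accept", "reject")))
  trials$rt <- NA_real_
  for (ch in c("accept", "reject")) {
    sel <- trials$choice == ch
    if (any(sel))
      trials$rt[sel] <- draw_rt(sum(sel), mean_rt[group, ch], config$rt_sdlog)
  }
  trials$duration <- ifelse(resp, trials$rt, 3.0)
  # re-time onsets with realized display durations, keeping the session ITIs
  for (r in unique(trials$run)) {
    idx <- which(trials$run == r)
    iti <- diff(c(0, trials$onset[idx])) -
      c(0, rep(3.25, length(idx) - 1L))
    t_cur <- 0
    for (jj in seq_along(idx)) {
      i <- idx[jj]
      trials$onset[i] <- t_cur + iti[jj]
      t_cur <- trials$onset[i] + trials$duration[i] + 0.25
    }
  }
  list(trials = trials, group = group, k = k, b = b)
}

# AR(1) Gaussian noise with marginal SD `sd` and lag-1 correlation `rho`.
ar1_noise <- function(n, sd, rho) {
  w <- stats::rnorm(n, 0, sd * sqrt(1 - rho^2))
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd)
  for (t in 2:n) x[t] <- rho * x[t - 1] + w[t]
  x
}

#' Simulate a subject's two-region BOLD series from the DCM forward model
#'
#' Drives the family-1 generative model (rdSV to vmPFC, Accept to dlPFC) with
#' the subject's realized event streams and ground-truth parameters, then
#' adds AR(1) Gaussian observation noise.
#'
#' @param behavior Output of [simulate_subject_behavior()].
#' @param theta_runs List (one per run) of named ground-truth parameter
#'   vectors.
#' @param config A `cohort_config`.
#' @param noise_seed Seed for the observation noise.
#' @return List of per-run matrices (`volumes_per_run` x 2, columns `d`, `v`).
#' @export
simulate_subject_bold <- function(behavior, theta_runs, config, noise_seed) {
  spec <- dcm_spec(family = 1L)
  rdsv <- rdsv_series(behavior$trials, list(k = behavior$k), behavior$group)
  runs <- seq_len(config$runs_per_subject)   # behavior always spans 2 runs;
  stopifnot(all(runs %in% behavior$trials$run),  # BOLD only for configured ones
            length(theta_runs) == length(runs))
  rng <- local_rng(noise_seed)
  on.exit(restore_rng(rng))
  out <- vector("list", length(runs))
  for (ri in seq_along(runs)) {
    sel <- behavior$trials$run == runs[ri]
    inputs <- build_input_set(behavior$trials[sel, , drop = FALSE],
                              rdsv[sel], config$volumes_per_run,
                              config$tr_seconds, config$dt)
    y <- dcm_forward(theta_runs[[ri]], spec, inputs)
    noise <- cbind(ar1_noise(nrow(y), config$bold_noise_sd, config$bold_ar1),
                   ar1_noise(nrow(y), config$bold_noise_sd, config$bold_ar1))
    out[[ri]] <- y + noise
  }
  names(out) <- paste0("run", runs)
  out
}

#' Plant the between-subject prediction effect into a cohort's ground truth
#'
#' Sets each subject's value of one ground-truth DCM parameter (by default
#' the later-choice d->v modulation) to a linear function of the
#' standardized negative log discount rate plus Gaussian scatter, then
#' regenerates the BOLD series from the updated ground truth. With
#' `effect_size = 0` the planted parameter is pure scatter (null cohort).
#'
#' @param cohort A `cohort` object from [simulate_cohort()].
#' @param effect_size Hz per SD of -log k.
#' @param effect_noise_sd Scatter SD (defaults to the cohort config value).
#' @param parameter Ground-truth parameter carrying the effect; its cohort
#'   mean stays at the [ground-truth default][cohort_config].
#' @return The cohort with updated ground truth and regenerated BOLD.
#' @export
plant_prediction_effect <- function(cohort, effect_size,
                                    effect_noise_sd = NULL,
                                    parameter = "later.d_to_v") {
  cfg <- cohort$config
  if (is.null(effect_noise_sd)) effect_noise_sd <- cfg$effect_noise_sd
  if (effect_size < 0) stop("effect size must be non-negative")
  base <- if (parameter == "later.d_to_v") cfg$later_dv_base
          else ground_truth_means()[[parameter]]
  logk <- log(cohort$ground_truth$k)
  zneg <- -(logk - mean(logk)) / max(stats::sd(logk), 1e-12)
  rng <- local_rng(derive_seed(cfg$seed, "plant"))
  planted <- base + effect_size * zneg +
    stats::rnorm(length(logk), 0, effect_noise_sd)
  restore_rng(rng)
  for (i in seq_along(cohort$subjects)) {
    for (r in seq_along(cohort$ground_truth$theta[[i]])) {
      cohort$ground_truth$theta[[i]][[r]][parameter] <- planted[i]
    }
    cohort$subjects[[i]]$bold <- simulate_subject_bold(
      cohort$ground_truth$behavior[[i]],
      cohort$ground_truth$theta[[i]], cfg,
      noise_seed = derive_seed(cfg$seed, "bold", i))
  }
  cohort$ground_truth$planted_parameter <- parameter
  cohort$ground_truth$planted_values <- planted
  if (parameter == "later.d_to_v")
    cohort$ground_truth$planted_later_d_to_v <- planted
  cohort
}

#' Build a cohort whose discounting signal lives only in the dlPFC series
#'
#' Specificity-test construction: the d->v transfer is silenced in the
#' ground truth (fixed, all-choices and later-choices d->v set to 0) and the
#' between-subject effect is planted in the Accept input gain to dlPFC.
#' vmPFC then carries no information about the discount rate, so replacing
#' the dlPFC series must drive prediction to chance.
#'
#' @param config A `cohort_config` (its `effect_size` is used for the
#'   planted Accept->d gain).
#' @return A `cohort`.
#' @export
simulate_dlpfc_effect_cohort <- function(config) {
  base_cfg <- config
  base_cfg$effect_size <- 0
  cohort <- simulate_cohort(base_cfg)
  for (i in seq_along(cohort$ground_truth$theta)) {
    for (r in seq_along(cohort$ground_truth$theta[[i]])) {
      cohort$ground_truth$theta[[i]][[r]][c("fixed.d_to_v", "all.d_to_v",
                                            "later.d_to_v")] <- 0
    }
  }
  cohort$config <- config
  plant_prediction_effect(cohort, config$effect_size,
                          parameter = "drive.accept_to_d")
}

#' Simulate a full synthetic cohort
#'
#' Draws per-subject behavioral parameters, realizes choices/RTs on the
#' offer grid, draws ground-truth DCM parameters (cohort means plus subject
#' and run scatter, with the later-choice d->v modulation linked to -log k by
#' the configured effect size), and integrates the forward model to produce
#' noisy two-region BOLD per run. Ground truth is stored separately from the
#' observed data; estimation code consumes `cohort$subjects` only.
#'
#' @param config A `cohort_config`.
#' @return List of class `cohort`: `config`, `subjects` (each: `id`,
#'   `trials`, `group`, `bold`), `ground_truth` (`k`, `b`, `theta`,
#'   `planted_later_d_to_v`, `behavior`).
#' @export
simulate_cohort <- function(config) {
  grid <- load_offer_grid()
  n <- config$n_subjects
  subjects <- vector("list", n)
  gt_theta <- vector("list", n)
  behaviors <- vector("list", n)
  k <- numeric(n); b <- numeric(n)
  means <- ground_truth_means()
  for (i in seq_len(n)) {
    beh <- simulate_subject_behavior(config, i, grid = grid)
    behaviors[[i]] <- beh
    k[i] <- beh$k; b[i] <- beh$b
    rng <- local_rng(derive_seed(config$seed, "theta", i))
    base <- means + stats::rnorm(length(means), 0, config$theta_jitter_sd)
    runs <- lapply(seq_len(config$runs_per_subject), function(r)
      stats::setNames(base + stats::rnorm(length(means), 0,
                                          config$run_jitter_sd),
                      names(means)))
    restore_rng(rng)
    gt_theta[[i]] <- runs
    subjects[[i]] <- list(id = i, trials = beh$trials, group = beh$group,
                          bold = NULL)
  }
  cohort <- structure(list(config = config, subjects = subjects,
                           ground_truth = list(k = k, b = b,
                                               theta = gt_theta,
                                               behavior = behaviors)),
                      class = "cohort")
  # planting regenerates the BOLD series, so it doubles as the generator
  plant_prediction_effect(cohort, config$effect_size)
}

#' Write / read a cohort to plain-text files
#'
#' Events as tab-separated tables, BOLD series as CSV (`time, region_d,
#' region_v`), ground truth and config as JSON sidecars, plus a manifest
#' with seeds and SHA-like checksums of every file.
#'
#' @param cohort A `cohort`.
#' @param dir Output directory (created if needed).
#' @return `write_cohort` returns the manifest invisibly; `read_cohort`
#'   returns a `cohort` (without ground-truth behavior closures).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (s in cohort$subjects) {
    ef <- file.path(dir, sprintf("sub-%02d_events.tsv", s$id))
    write_events(s$trials, ef)
    files <- c(files, ef)
    for (rn in names(s$bold)) {
      bf <- file.path(dir, sprintf("sub-%02d_%s_bold.csv", s$id, rn))
      y <- s$bold[[rn]]
      utils::write.csv(data.frame(
        time = (seq_len(nrow(y)) - 1) * cohort$config$tr_seconds,
        region_d = y[, 1], region_v = y[, 2]), bf, row.names = FALSE)
      files <- c(files, bf)
    }
  }
  gt <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(list(k = cohort$ground_truth$k,
                            b = cohort$ground_truth$b,
                            planted_later_d_to_v =
                              cohort$ground_truth$planted_later_d_to_v,
                            theta = cohort$ground_truth$theta),
                       gt, auto_unbox = TRUE, digits = 12)
  cf <- file.path(dir, "config.json")
  jsonlite::write_json(unclass(cohort$config), cf, auto_unbox = TRUE,
                       digits = 12)
  files <- c(files, gt, cf)
  manifest <- data.frame(file = basename(files),
                         checksum = vapply(files, file_checksum, character(1)),
                         row.names = NULL)
  jsonlite::write_json(list(seed = cohort$config$seed, files = manifest),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(manifest)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  config <- do.call(cohort_config, cfg[setdiff(names(cfg),
                                               character(0))])
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  ev_files <- sort(list.files(dir, "_events\\.tsv$", full.names = TRUE))
  subjects <- lapply(seq_along(ev_files), function(i) {
    trials <- read_events(ev_files[i])
    bold_files <- sort(list.files(
      dir, sprintf("sub-%02d_run.*_bold\\.csv$", i), full.names = TRUE))
    bold <- lapply(bold_files, function(f) {
      d <- utils::read.csv(f)
      as.matrix(d[, c("region_d", "region_v")])
    })
    names(bold) <- paste0("run", seq_along(bold))
    list(id = i, trials = trials, group = assign_group(trials), bold = bold)
  })
  structure(list(config = config, subjects = subjects,
                 ground_truth = gt),
            class = "cohort")
}

file_checksum <- function(path) {
  # order-sensitive 64-bit FNV-style hash over the file bytes, hex-encoded
  bytes <- as.integer(readBin(path, "raw", file.info(path)$size))
  h <- 1469598103934665
  for (chunk in split(bytes, ceiling(seq_along(bytes) / 4096))) {
    h <- (h * 31 + sum(chunk * seq_along(chunk))) %% 2^52
  }
  paste0(format(as.hexmode(as.integer(h %/% 2^26)), width = 7),
         format(as.hexmode(as.integer(h %% 2^26)), width = 7))
}
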