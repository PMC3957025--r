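#' Balanced accuracy from a confusion matrix
#'
#' `(TP / (TP + FN) + TN / (TN + FP)) / 2` — the mean of sensitivity and
#' specificity, which corrects plain accuracy for class imbalance.
#'
#' @param cm Named vector or list with `TP`, `FN`, `TN`, `FP` counts.
#' @return Balanced accuracy in \[0, 1\].
#' @export
balanced_accuracy <- function(cm) {
  cm <- unlist(cm)[c("TP", "FN", "TN", "FP")]
  if (anyNA(cm) || any(cm < 0)) stop("confusion matrix needs TP, FN, TN, FP >= 0")
  if (cm["TP"] + cm["FN"] == 0 || cm["TN"] + cm["FP"] == 0)
    stop("balanced accuracy undefined with an empty class")
  unname(0.5 * (cm["TP"] / (cm["TP"] + cm["FN"]) +
                  cm["TN"] / (cm["TN"] + cm["FP"])))
}

# Beta-posterior credible interval for balanced accuracy: independent
# Beta(count+1, count+1) posteriors on sensitivity and specificity, averaged
# by Monte-Carlo.
balanced_accuracy_interval <- function(cm, level = 0.95, seed = 1L,
                                       n_draws = 2e5) {
  cm <- unlist(cm)
  rng <- local_rng(seed)
  sens <- stats::rbeta(n_draws, cm["TP"] + 1, cm["FN"] + 1)
  spc <- stats::rbeta(n_draws, cm["TN"] + 1, cm["FP"] + 1)
  restore_rng(rng)
  q <- stats::quantile((sens + spc) / 2,
                       c((1 - level) / 2, 1 - (1 - level) / 2))
  unname(q)
}

#' Extract the DCM feature table from a cohort
#'
#' Runs the estimation path on observed data only: fits the discounting model
#' per subject, recodes rdSV from the fitted parameters, builds the input
#' streams, and inverts the family-1 full DCM per run. Features are the
#' posterior means of the 12 coupling/modulation/input parameters per run
#' (hemodynamic constants are fixed, hence excluded); the target is the
#' fitted log k.
#'
#' @param cohort A `cohort` (only `cohort$subjects` and `cohort$config` are
#'   read).
#' @param spec DCM specification used for inversion (family-1 full model).
#' @param max_iter Gauss-Newton iteration cap per inversion.
#' @return List of class `feature_table`: `features` (subjects x
#'   (12 x runs) matrix, columns `run<r>.<parameter>`), `target` (fitted
#'   log k), `group`, `fits`, `posteriors`.
#' @export
extract_features <- function(cohort, spec = dcm_spec(family = 1L),
                             max_iter = 24L) {
  cfg <- cohort$config
  n <- length(cohort$subjects)
  feats <- NULL
  target <- numeric(n)
  fits <- vector("list", n)
  posts <- vector("list", n)
  for (i in seq_len(n)) {
    s <- cohort$subjects[[i]]
    fit <- fit_discounting(s$trials)
    fits[[i]] <- fit
    target[i] <- log(fit$k)
    grp <- assign_group(s$trials)
    rdsv <- rdsv_series(s$trials, fit, grp)
    row <- numeric(0)
    posts[[i]] <- vector("list", length(s$bold))
    for (r in seq_along(s$bold)) {
      sel <- s$trials$run == r
      inputs <- build_input_set(s$trials[sel, , drop = FALSE], rdsv[sel],
                                cfg$volumes_per_run, cfg$tr_seconds, cfg$dt)
      post <- dcm_invert(s$bold[[r]], spec, inputs, max_iter = max_iter)
      posts[[i]][[r]] <- post
      v <- post$mean
      names(v) <- paste0("run", r, ".", names(v))
      row <- c(row, v)
    }
    feats <- rbind(feats, row)
  }
  rownames(feats) <- NULL
  structure(list(features = feats, target = target,
                 group = vapply(cohort$subjects, `[[`, character(1), "group"),
                 fits = fits, posteriors = posts),
            class = "feature_table")
}

#' Leave-one-subject-out elastic-net prediction of log discount rates
#'
#' For each held-out subject, an elastic net (mixing `alpha`, penalty chosen
#' by seeded 5-fold cross-validation within the training subjects unless a
#' fixed `lambda` is given) is fit on the remaining subjects' features;
#' the held-out subject's continuous log k is predicted and classified as
#' above/below the training-set mean. Standardization, penalty selection and
#' the class threshold all use training data only. Aggregates the confusion
#' matrix, balanced accuracy with a Beta-posterior 95% interval, and the
#' Spearman rank correlation of predicted vs. true log k.
#'
#' @param features Matrix (subjects x predictors) or a `feature_table`.
#' @param target True log k per subject (taken from a `feature_table` when
#'   omitted).
#' @param alpha Elastic-net mixing parameter (default 0.3).
#' @param lambda Fixed penalty; `NULL` selects by inner cross-validation.
#' @param seed Seed for fold assignment and the interval draws.
#' @return List of class `prediction_result`: `predicted`, `true`,
#'   `predicted_label`, `true_label`, `confusion` (TP, FN, TN, FP),
#'   `balanced_accuracy`, `interval`, `spearman_rho`, `spearman_p`,
#'   `flagged_folds`.
#' @export
loo_predict <- function(features, target = NULL, alpha = 0.3, lambda = NULL,
                        seed = 1L) {
  if (inherits(features, "feature_table")) {
    if (is.null(target)) target <- features$target
    features <- features$features
  }
  X <- as.matrix(features)
  y <- target
  n <- nrow(X)
  if (n < 4L) stop("need at least 4 subjects")
  pred <- numeric(n)
  pred_lab <- logical(n)
  true_lab <- logical(n)
  flagged <- integer(0)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]; ytr <- y[-i]
    if (stats::sd(ytr) == 0) { flagged <- c(flagged, i); pred[i] <- mean(ytr) }
    else {
      lam <- lambda
      if (is.null(lam))
        lam <- cv_elastic_net(Xtr, ytr, alpha = alpha,
                              seed = derive_seed(seed, "cv", i))$lambda
      fit <- elastic_net_fit(Xtr, ytr, alpha = alpha, lambda = lam,
                             tol = 1e-8)
      pred[i] <- predict_enet(fit, X[i, , drop = FALSE])
    }
    thr <- mean(ytr)
    pred_lab[i] <- pred[i] > thr
    true_lab[i] <- y[i] > thr
  }
  cm <- c(TP = sum(pred_lab & true_lab), FN = sum(!pred_lab & true_lab),
          TN = sum(!pred_lab & !true_lab), FP = sum(pred_lab & !true_lab))
  ba <- balanced_accuracy(cm)
  ci <- balanced_accuracy_interval(cm, seed = derive_seed(seed, "interval"))
  ct <- suppressWarnings(stats::cor.test(pred, y, method = "spearman"))
  structure(list(predicted = pred, true = y,
                 predicted_label = pred_lab, true_label = true_lab,
                 confusion = cm, balanced_accuracy = ba, interval = ci,
                 spearman_rho = unname(ct$estimate),
                 spearman_p = ct$p.value,
                 flagged_folds = flagged),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf(
    "prediction_result: MBA = %.3f (95%% interval %.3f-%.3f), rho = %.3f (p = %.3g)\n",
    x$balanced_accuracy, x$interval[1], x$interval[2],
    x$spearman_rho, x$spearman_p))
  cat(sprintf("  confusion: TP=%d FN=%d TN=%d FP=%d\n",
              x$confusion["TP"], x$confusion["FN"],
              x$confusion["TN"], x$confusion["FP"]))
  invisible(x)
}

#' Standard feature-column ablation groups
#'
#' Column groups (matched by parameter name across runs) used in the
#' specificity analyses: local driving/self parameters of each region and the
#' directed between-region connectivity sets.
#'
#' @return Named list of regular expressions over feature-column names.
#' @export
ablation_groups <- function() {
  list(vmpfc_local = "(drive\\.value_to_v|all\\.v_self|later\\.v_self)$",
       dlpfc_local = "(drive\\.accept_to_d|all\\.d_self|later\\.d_self)$",
       d_to_v = "\\.d_to_v$",
       v_to_d = "\\.v_to_d$")
}

#' Re-run the prediction with named feature groups removed
#'
#' Parameters are never re-estimated: columns are dropped from the elastic
#' net regression only, so the remaining features are exactly those of the
#' original fully connected model.
#'
#' @param features `feature_table` or matrix.
#' @param target Log k vector (if `features` is a matrix).
#' @param groups Named list of regexes over column names (default
#'   [ablation_groups()]); each entry produces one ablated re-run. An empty
#'   regex (`""`) drops nothing.
#' @param ... Passed to [loo_predict()].
#' @return Named list of `prediction_result`, one per group.
#' @export
ablation_suite <- function(features, target = NULL,
                           groups = ablation_groups(), ...) {
  if (inherits(features, "feature_table")) {
    if (is.null(target)) target <- features$target
    features <- features$features
  }
  X <- as.matrix(features)
  lapply(groups, function(rx) {
    drop <- if (nzchar(rx)) grepl(rx, colnames(X)) else rep(FALSE, ncol(X))
    if (all(drop)) stop("ablation would drop every feature column")
    loo_predict(X[, !drop, drop = FALSE], target, ...)
  })
}

#' Region-swap specificity test
#'
#' Replaces the dlPFC (region d) series of every subject and run, re-runs the
#' DCM inversion and the leave-one-out prediction, and returns the new
#' prediction result. With an independent-noise replacement the planted
#' d->v effect cannot survive, so accuracy should fall to chance.
#'
#' @param cohort A `cohort`.
#' @param replacement Either `"noise"` (independent Gaussian series matched
#'   to each run's region-d marginal SD), `"copy"` (keep the true region;
#'   identity control), or a list `replacement[[subject]][[run]]` of vectors.
#' @param seed Seed for the noise replacement and prediction folds.
#' @param ... Passed to [extract_features()] / [loo_predict()].
#' @return List: `prediction` (a `prediction_result`), `features`.
#' @export
specificity_swap <- function(cohort, replacement = "noise", seed = 1L, ...) {
  swapped <- cohort
  for (i in seq_along(swapped$subjects)) {
    for (r in seq_along(swapped$subjects[[i]]$bold)) {
      y <- swapped$subjects[[i]]$bold[[r]]
      repl <- if (identical(replacement, "copy")) y[, 1]
      else if (identical(replacement, "noise")) {
        rng <- local_rng(derive_seed(seed, "swap", i * 100L + r))
        out <- stats::rnorm(nrow(y), mean(y[, 1]), stats::sd(y[, 1]))
        restore_rng(rng)
        out
      } else replacement[[i]][[r]]
      if (length(repl) != nrow(y))
        stop("replacement series must match the region-d series length")
      y[, 1] <- repl
      swapped$subjects[[i]]$bold[[r]] <- y
    }
  }
  ft <- extract_features(swapped, ...)
  list(prediction = loo_predict(ft, seed = seed), features = ft)
}
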