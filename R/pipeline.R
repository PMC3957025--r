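#' Assemble a pipeline configuration
#'
#' Bundles the cohort design, model-selection and prediction options, and the
#' global seed into one serializable object. Every stochastic stage of
#' [run_pipeline()] receives a seed derived from the global seed and the
#' stage name, so identical configurations reproduce identical reports.
#'
#' @param seed Global integer seed.
#' @param cohort A `cohort_config` (defaults to the study design under the
#'   derived cohort seed).
#' @param model_subset `"family_full"` (invert the four family-full models;
#'   the default desk-scale model space), `"all"` (all 64), or an integer
#'   vector of model indices into [enumerate_models()].
#' @param bms_draws Dirichlet draws for exceedance probabilities.
#' @param enet_alpha Elastic-net mixing parameter.
#' @param enet_lambda Fixed penalty or `NULL` for inner cross-validation.
#' @param dcm_max_iter Gauss-Newton iteration cap per DCM inversion.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed, cohort = NULL,
                            model_subset = "family_full",
                            bms_draws = 1e5, enet_alpha = 0.3,
                            enet_lambda = NULL, dcm_max_iter = 24L) {
  if (is.null(cohort))
    cohort <- cohort_config(seed = derive_seed(seed, "cohort"))
  structure(list(seed = as.integer(seed), cohort = cohort,
                 model_subset = model_subset,
                 bms_draws = bms_draws, enet_alpha = enet_alpha,
                 enet_lambda = enet_lambda,
                 dcm_max_iter = as.integer(dcm_max_iter)),
            class = "pipeline_config")
}

#' Save / load a pipeline configuration (YAML round trip)
#'
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @return `load_pipeline_config` returns a `pipeline_config` equal to the
#'   one saved.
#' @export
save_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$cohort <- unclass(x$cohort)
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname save_pipeline_config
#' @export
load_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  cohort <- do.call(cohort_config, x$cohort)
  pipeline_config(seed = x$seed, cohort = cohort,
                  model_subset = if (is.character(x$model_subset))
                    x$model_subset else as.integer(x$model_subset),
                  bms_draws = x$bms_draws, enet_alpha = x$enet_alpha,
                  enet_lambda = x$enet_lambda,
                  dcm_max_iter = x$dcm_max_iter)
}

write_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 12, pretty = TRUE)
  invisible(path)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Stages: `simulate` (generate and write the cohort), `behavior` (discount
#' fits and group assignment), `glm` (region GLMs, group contrasts, full vs
#' reduced value-model comparison), `dcm` (invert the configured model
#' subset, always including the family-1 full model), `bms` (family-level
#' random-effects model selection, Bayesian parameter averaging and
#' connectivity tests on the full model), `predict` (leave-one-out elastic
#' net with ablations). Each stage writes one JSON report to `out_dir`; a
#' stage whose report already exists is skipped unless `overwrite = TRUE`,
#' so a deleted downstream report is recomputed from the cached upstream
#' state. A manifest lists every written file with a checksum.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Output directory.
#' @param stages Stages to run, in order.
#' @param overwrite Recompute stages whose reports exist?
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "behavior", "glm", "dcm",
                                    "bms", "predict"),
                         overwrite = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  log_stage <- function(stage, msg = "done") {
    message(sprintf("[%s] stage=%s seed=%d elapsed=%.1fs %s",
                    format(Sys.time(), "%H:%M:%S"), stage, config$seed,
                    as.numeric(difftime(Sys.time(), t0, units = "secs")),
                    msg))
  }
  results <- list()
  cohort <- NULL
  need_cohort <- function() {
    if (is.null(cohort)) {
      cdir <- file.path(out_dir, "cohort")
      if (file.exists(file.path(cdir, "manifest.json")) && !overwrite) {
        cohort <<- read_cohort(cdir)
      } else {
        cohort <<- simulate_cohort(config$cohort)
      }
    }
    cohort
  }

  if ("simulate" %in% stages) {
    cdir <- file.path(out_dir, "cohort")
    if (overwrite || !file.exists(file.path(cdir, "manifest.json"))) {
      cohort <- simulate_cohort(config$cohort)
      write_cohort(cohort, cdir)
    }
    log_stage("simulate")
  }

  if ("behavior" %in% stages) {
    path <- file.path(out_dir, "behavior.json")
    if (overwrite || !file.exists(path)) {
      co <- need_cohort()
      fits <- lapply(co$subjects, function(s) fit_discounting(s$trials))
      tab <- data.frame(
        subject = vapply(co$subjects, `[[`, integer(1), "id"),
        k = vapply(fits, `[[`, numeric(1), "k"),
        b = vapply(fits, `[[`, numeric(1), "b"),
        loglik = vapply(fits, `[[`, numeric(1), "loglik"),
        group = vapply(co$subjects, `[[`, character(1), "group"))
      write_report(list(fits = tab,
                        n_wait_group = sum(tab$group == "WG"),
                        n_now_group = sum(tab$group == "NG")), path)
    }
    results$behavior <- jsonlite::read_json(path, simplifyVector = TRUE)
    log_stage("behavior")
  }

  if ("glm" %in% stages) {
    path <- file.path(out_dir, "glm.json")
    if (overwrite || !file.exists(path)) {
      co <- need_cohort()
      cfg <- co$config
      value_t <- accept_t <- numeric(0)
      series_v <- list(); designs <- list()
      for (s in co$subjects) {
        fit <- fit_discounting(s$trials)
        rdsv <- rdsv_series(s$trials, fit, assign_group(s$trials))
        scanned <- s$trials$run <= length(s$bold)   # runs with BOLD acquired
        ch <- s$trials$choice[scanned]
        # the Accept contrast needs both choice types in the scanned runs
        if (!all(c("accept", "reject") %in% ch)) next
        des <- build_design(s$trials[scanned, , drop = FALSE], rdsv[scanned],
                            cfg$volumes_per_run, cfg$tr_seconds, cfg$dt)
        y_v <- unlist(lapply(s$bold, function(m) m[, 2]))
        y_d <- unlist(lapply(s$bold, function(m) m[, 1]))
        g_v <- fit_glm(y_v, des)
        g_d <- fit_glm(y_d, des)
        value_t <- c(value_t, g_v$contrasts$value$t)
        accept_t <- c(accept_t, g_d$contrasts$accept$t)
        series_v[[length(series_v) + 1L]] <- y_v
        designs[[length(designs) + 1L]] <- des
      }
      cmp <- compare_full_vs_reduced(series_v, designs,
                                     seed = derive_seed(config$seed, "glm"),
                                     n_draws = config$bms_draws)
      gv <- group_ttest(value_t); ga <- group_ttest(accept_t)
      write_report(list(
        group_value_t = gv$t, group_value_p = gv$p,
        group_accept_t = ga$t, group_accept_p = ga$p,
        exceedance_full_vs_reduced = cmp$exceedance_full), path)
    }
    results$glm <- jsonlite::read_json(path, simplifyVector = TRUE)
    log_stage("glm")
  }

  dcm_needed <- any(c("dcm", "bms", "predict") %in% stages)
  features_path <- file.path(out_dir, "features.csv")
  evidence_path <- file.path(out_dir, "dcm_evidence.csv")
  if (dcm_needed && ("dcm" %in% stages) &&
      (overwrite || !file.exists(features_path))) {
    co <- need_cohort()
    space <- enumerate_models()
    subset_idx <- if (identical(config$model_subset, "family_full"))
      space$full_model
    else if (identical(config$model_subset, "all")) seq_along(space$specs)
    else as.integer(config$model_subset)
    subset_idx <- sort(unique(c(subset_idx,
                                space$full_model[space$family[space$full_model] == 1L])))
    ft <- extract_features(co, max_iter = config$dcm_max_iter)
    utils::write.csv(cbind(as.data.frame(ft$features),
                           target_logk = ft$target),
                     features_path, row.names = FALSE)
    # per-model evidences (first run) for model/family selection
    ev <- matrix(NA_real_, length(co$subjects), length(subset_idx))
    for (i in seq_along(co$subjects)) {
      s <- co$subjects[[i]]
      fit <- ft$fits[[i]]
      rdsv <- rdsv_series(s$trials, fit, assign_group(s$trials))
      sel <- s$trials$run == 1L
      inputs <- build_input_set(s$trials[sel, , drop = FALSE], rdsv[sel],
                                co$config$volumes_per_run,
                                co$config$tr_seconds, co$config$dt)
      for (mi in seq_along(subset_idx)) {
        # family-1 full model already inverted during feature extraction
        sp <- space$specs[[subset_idx[mi]]]
        if (subset_idx[mi] == space$full_model[1] &&
            !is.null(ft$posteriors[[i]][[1]])) {
          ev[i, mi] <- ft$posteriors[[i]][[1]]$free_energy
        } else {
          ev[i, mi] <- dcm_invert(s$bold[[1]], sp, inputs,
                                  max_iter = config$dcm_max_iter)$free_energy
        }
      }
    }
    colnames(ev) <- paste0("model", subset_idx)
    utils::write.csv(cbind(ev, family = NA), evidence_path, row.names = FALSE)
    ev_df <- as.data.frame(ev)
    attr(ev_df, "family") <- space$family[subset_idx]
    utils::write.csv(data.frame(model = subset_idx,
                                family = space$family[subset_idx]),
                     file.path(out_dir, "model_index.csv"), row.names = FALSE)
    results$dcm <- list(features = ft, evidence = ev,
                        family = space$family[subset_idx])
    log_stage("dcm")
  } else if (dcm_needed && file.exists(features_path)) {
    fdat <- utils::read.csv(features_path, check.names = FALSE)
    ft <- structure(list(features = as.matrix(fdat[, setdiff(names(fdat),
                                                             "target_logk")]),
                         target = fdat$target_logk),
                    class = "feature_table")
    ev <- NULL; fam <- NULL
    if (file.exists(evidence_path)) {
      edat <- utils::read.csv(evidence_path)
      ev <- as.matrix(edat[, grep("^model", names(edat)), drop = FALSE])
      midx <- utils::read.csv(file.path(out_dir, "model_index.csv"))
      fam <- midx$family
    }
    results$dcm <- list(features = ft, evidence = ev, family = fam)
    log_stage("dcm", "cached")
  }

  if ("bms" %in% stages && !is.null(results$dcm$evidence)) {
    path <- file.path(out_dir, "bms.json")
    if (overwrite || !file.exists(path)) {
      fb <- family_bms(results$dcm$evidence, results$dcm$family,
                       seed = derive_seed(config$seed, "bms"),
                       n_draws = config$bms_draws)
      rep <- list(family_exceedance = as.list(fb$exceedance),
                  family_expected_prob = as.list(fb$expected_prob))
      if (!is.null(results$dcm$features$posteriors)) {
        posts <- lapply(results$dcm$features$posteriors, `[[`, 1)
        ct <- connectivity_tests(posts)
        rep$connectivity <- ct
      }
      write_report(rep, path)
    }
    results$bms <- jsonlite::read_json(path, simplifyVector = TRUE)
    log_stage("bms")
  }

  if ("predict" %in% stages && !is.null(results$dcm$features)) {
    path <- file.path(out_dir, "prediction.json")
    if (overwrite || !file.exists(path)) {
      ft <- results$dcm$features
      pr <- loo_predict(ft, alpha = config$enet_alpha,
                        lambda = config$enet_lambda,
                        seed = derive_seed(config$seed, "predict"))
      abl <- ablation_suite(ft, alpha = config$enet_alpha,
                            lambda = config$enet_lambda,
                            seed = derive_seed(config$seed, "predict"))
      write_report(list(
        balanced_accuracy = pr$balanced_accuracy,
        interval = pr$interval,
        spearman_rho = pr$spearman_rho, spearman_p = pr$spearman_p,
        confusion = as.list(pr$confusion),
        ablations = lapply(abl, function(a)
          list(balanced_accuracy = a$balanced_accuracy,
               spearman_rho = a$spearman_rho))), path)
    }
    results$prediction <- jsonlite::read_json(path, simplifyVector = TRUE)
    log_stage("predict")
  }

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- data.frame(file = sub(paste0("^", out_dir, "/?"), "", files),
                         checksum = vapply(files, file_checksum,
                                           character(1)))
  rownames(manifest) <- NULL
  write_report(list(seed = config$seed, files = manifest),
               file.path(out_dir, "pipeline_manifest.json"))
  invisible(results)
}
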