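#' Default hemodynamic constants for the balloon observation model
#'
#' Literature-default balloon/windkessel constants, fixed (not estimated)
#' so that the two-region inversion stays well conditioned: signal decay
#' `kappa`, autoregulation `gamma`, transit time `tau`, stiffness `alpha`,
#' resting oxygen extraction `E0`, resting venous volume fraction `V0`.
#'
#' @return Named numeric vector of the six constants.
#' @export
dcm_hemo_constants <- function() {
  c(kappa = 0.64, gamma = 0.32, tau = 2.0, alpha = 0.32, E0 = 0.4, V0 = 0.04)
}

#' Specify a two-region bilinear DCM
#'
#' Regions are `d` (dlPFC-BA46) and `v` (vmPFC). The fixed coupling matrix
#' carries free off-diagonal connections and stability-constrained
#' self-connections (`-0.5 * exp(theta)`, theta fixed at 0). Two modulatory
#' conditions — all choice periods and later (accepted) choice periods —
#' scale couplings bilinearly; between-region modulations are switchable per
#' model, self-modulations are always present. Two driving inputs (the
#' trial-wise rdSV stream and the Accept event stream) enter the regions
#' determined by the model family:
#' family 1 = rdSV to v, Accept to d; family 2 = both to v;
#' family 3 = both to d; family 4 = rdSV to d, Accept to v.
#'
#' @param family Driving-input family, 1--4.
#' @param mod_on Named logical vector switching the four between-region
#'   modulations `all.d_to_v`, `all.v_to_d`, `later.d_to_v`, `later.v_to_d`.
#' @param prior_var_coupling Prior variance for couplings and modulations.
#' @param prior_var_drive Prior variance for driving-input gains.
#' @return List of class `dcm_spec` with `par_names`, `prior_mean`,
#'   `prior_var`, `family`, `mod_on`.
#' @export
dcm_spec <- function(family = 1L,
                     mod_on = c(all.d_to_v = TRUE, all.v_to_d = TRUE,
                                later.d_to_v = TRUE, later.v_to_d = TRUE),
                     prior_var_coupling = 1 / 16,
                     prior_var_drive = 1) {
  stopifnot(family %in% 1:4)
  switches <- c(all.d_to_v = TRUE, all.v_to_d = TRUE,
                later.d_to_v = TRUE, later.v_to_d = TRUE)
  switches[names(mod_on)] <- mod_on
  drive_names <- switch(family,
    c("drive.value_to_v", "drive.accept_to_d"),
    c("drive.value_to_v", "drive.accept_to_v"),
    c("drive.value_to_d", "drive.accept_to_d"),
    c("drive.value_to_d", "drive.accept_to_v"))
  par_names <- c("fixed.v_to_d", "fixed.d_to_v",
                 if (switches["all.v_to_d"]) "all.v_to_d",
                 "all.v_self",
                 if (switches["all.d_to_v"]) "all.d_to_v",
                 "all.d_self",
                 if (switches["later.v_to_d"]) "later.v_to_d",
                 "later.v_self",
                 if (switches["later.d_to_v"]) "later.d_to_v",
                 "later.d_self",
                 drive_names)
  pv <- ifelse(grepl("^drive", par_names), prior_var_drive,
               prior_var_coupling)
  structure(list(par_names = par_names,
                 prior_mean = stats::setNames(rep(0, length(par_names)), par_names),
                 prior_var = stats::setNames(pv, par_names),
                 family = as.integer(family),
                 mod_on = switches),
            class = "dcm_spec")
}

# Expand a named parameter vector into the A, B (cube slices: all, later) and
# C matrices. Region index 1 = d, 2 = v; entry [i, j] couples region j to i.
theta_to_matrices <- function(theta, spec) {
  g <- function(nm) if (nm %in% names(theta)) unname(theta[nm]) else 0
  A <- matrix(c(-0.5, g("fixed.d_to_v"),
                g("fixed.v_to_d"), -0.5), 2, 2)
  B_all <- matrix(c(g("all.d_self"), g("all.d_to_v"),
                    g("all.v_to_d"), g("all.v_self")), 2, 2)
  B_later <- matrix(c(g("later.d_self"), g("later.d_to_v"),
                      g("later.v_to_d"), g("later.v_self")), 2, 2)
  C <- matrix(0, 2, 2)                # columns: value, accept
  C[2, 1] <- g("drive.value_to_v"); C[1, 1] <- g("drive.value_to_d")
  C[2, 2] <- g("drive.accept_to_v"); C[1, 2] <- g("drive.accept_to_d")
  list(A = A, B = list(all = B_all, later = B_later), C = C)
}

#' Bilinear neural state derivative
#'
#' `dz/dt = (A + sum_j u_mod[j] B_j) z + C u_drive` — the deterministic
#' bilinear dynamics at one instant. Exposed for testing and for building
#' reference integrations.
#'
#' @param z Neural state vector.
#' @param A Fixed coupling matrix.
#' @param B_list List of modulatory matrices, one per modulatory input.
#' @param C Driving gain matrix (regions x inputs).
#' @param u_mod Modulatory input values at this instant.
#' @param u_drive Driving input values at this instant.
#' @return Derivative vector, same length as `z`.
#' @export
neural_dynamics <- function(z, A, B_list, C, u_mod, u_drive) {
  if (length(u_mod) != length(B_list))
    stop("one modulatory input per B matrix required")
  if (nrow(A) != length(z) || ncol(C) != length(u_drive))
    stop("dimension mismatch in neural dynamics")
  Aeff <- A
  for (j in seq_along(B_list)) Aeff <- Aeff + u_mod[j] * B_list[[j]]
  as.numeric(Aeff %*% z + C %*% u_drive)
}

#' Balloon hemodynamic observation model (reference integrator)
#'
#' Integrates vasodilatory signal, inflow, volume and deoxyhemoglobin states
#' driven by a given neural series and returns percent-signal BOLD. This is
#' the R reference path; production forward simulation runs in compiled code.
#'
#' @param neural Matrix (microtime x regions) of neural activity.
#' @param dt Microtime step in seconds.
#' @param constants Hemodynamic constants, see [dcm_hemo_constants()].
#' @return Matrix (microtime x regions) of percent-signal BOLD.
#' @export
hemodynamics <- function(neural, dt, constants = dcm_hemo_constants()) {
  if (any(!is.finite(neural))) stop("neural series must be finite")
  neural <- as.matrix(neural)
  nr <- ncol(neural); nt <- nrow(neural)
  kappa <- constants["kappa"]; gam <- constants["gamma"]
  tau <- constants["tau"]; alpha <- constants["alpha"]
  E0 <- constants["E0"]; V0 <- constants["V0"]
  k1 <- 7 * E0; k2 <- 2; k3 <- 2 * E0 - 0.2
  st <- matrix(rep(c(0, 1, 1, 1), nr), 4, nr)   # s, f, v, q per region
  out <- matrix(0, nt, nr)
  dfun <- function(st, z) {
    f <- pmax(st[2, ], 1e-6); v <- pmax(st[3, ], 1e-6); q <- pmax(st[4, ], 1e-6)
    fout <- v^(1 / alpha)
    E <- 1 - (1 - E0)^(1 / f)
    rbind(z - kappa * st[1, ] - gam * (f - 1),
          st[1, ],
          (f - fout) / tau,
          (f * E / E0 - fout * q / v) / tau)
  }
  for (t in seq_len(nt)) {
    z <- neural[t, ]
    d1 <- dfun(st, z)
    d2 <- dfun(st + dt / 2 * d1, z)
    d3 <- dfun(st + dt / 2 * d2, z)
    d4 <- dfun(st + dt * d3, z)
    st <- st + dt / 6 * (d1 + 2 * d2 + 2 * d3 + d4)
    if (any(!is.finite(st)))
      stop("hemodynamic integration diverged (non-physical parameters?)")
    v <- pmax(st[3, ], 1e-6); q <- pmax(st[4, ], 1e-6)
    out[t, ] <- V0 * (k1 * (1 - q) + k2 * (1 - q / v) + k3 * (1 - v)) * 100
  }
  out
}

#' Build the microtime input streams for a session run
#'
#' Produces the five input streams the DCM uses, aligned on a shared
#' microtime clock: the all-choices boxcar (duration = RT), the later-choices
#' boxcar (accepted trials only), the rdSV-scaled driving stream (scaled by
#' the $25 reference so gains are order-one), the Accept driving stream, and
#' the fixation boxcar (complement of the choice periods).
#'
#' @param events Trial data frame for one run (`onset`, `rt`, `choice`).
#' @param rdsv Per-trial rdSV values aligned with `events`.
#' @param volumes Number of volumes in the run.
#' @param tr Repetition time (s).
#' @param dt Microtime step (s).
#' @param value_scale Divisor applied to rdSV (default 25, the reference).
#' @return List of class `dcm_inputs`: `u_mod` (microtime x 2: all, later),
#'   `u_drive` (microtime x 2: value, accept), `u_fix`, `sample_idx`, `dt`,
#'   `volumes`, `tr`.
#' @export
build_input_set <- function(events, rdsv, volumes, tr, dt = 0.1,
                            value_scale = 25) {
  stopifnot(length(rdsv) == nrow(events))
  ok <- !is.na(events$choice) & events$choice != "missed"
  ev <- events[ok, , drop = FALSE]
  rv <- rdsv[ok]
  run_dur <- volumes * tr
  if (any(ev$onset + ev$rt > run_dur))
    stop("event durations extend beyond the run")
  n_micro <- ceiling(run_dur / dt)
  acc <- ev$choice == "accept"
  u_all <- microtime_stream(ev$onset, ev$rt, rep(1, nrow(ev)), n_micro, dt)
  u_later <- microtime_stream(ev$onset[acc], ev$rt[acc],
                              rep(1, sum(acc)), n_micro, dt)
  u_value <- microtime_stream(ev$onset, ev$rt, rv / value_scale, n_micro, dt)
  u_accept <- u_later
  structure(list(u_mod = cbind(all = u_all, later = u_later),
                 u_drive = cbind(value = u_value, accept = u_accept),
                 u_fix = 1 - pmin(u_all, 1),
                 sample_idx = pmin(n_micro, floor(((seq_len(volumes) - 1L) * tr) / dt) + 1L),
                 dt = dt, volumes = volumes, tr = tr),
            class = "dcm_inputs")
}

#' Deterministic DCM forward simulation
#'
#' Integrates the bilinear neural dynamics and balloon hemodynamics (RK4 at
#' the microtime step) and samples BOLD on the TR grid.
#'
#' @param theta Named parameter vector (subset of the spec's `par_names`;
#'   absent parameters are 0).
#' @param spec A `dcm_spec`.
#' @param inputs A `dcm_inputs` object.
#' @param constants Hemodynamic constants.
#' @return Matrix (volumes x 2) of percent-signal BOLD, columns `d`, `v`.
#' @export
dcm_forward <- function(theta, spec, inputs, constants = dcm_hemo_constants()) {
  m <- theta_to_matrices(theta, spec)
  B <- array(0, c(2, 2, 2))
  B[, , 1] <- m$B$all; B[, , 2] <- m$B$later
  out <- dcm_integrate_cpp(m$A, B, m$C, inputs$u_mod, inputs$u_drive,
                           inputs$dt, inputs$sample_idx,
                           unname(constants))
  y <- out$bold
  colnames(y) <- c("d", "v")
  y
}

# Pure-R reference forward simulation: joint RK4 on the full 10-state system
# (neural + 4 hemodynamic states per region), mirroring the compiled
# integrator step for step; used to validate it on short inputs.
dcm_forward_r <- function(theta, spec, inputs, constants = dcm_hemo_constants()) {
  m <- theta_to_matrices(theta, spec)
  dt <- inputs$dt
  nt <- nrow(inputs$u_mod)
  kappa <- constants[["kappa"]]; gam <- constants[["gamma"]]
  tau <- constants[["tau"]]; alpha <- constants[["alpha"]]
  E0 <- constants[["E0"]]; V0 <- constants[["V0"]]
  k1 <- 7 * E0; k2 <- 2; k3 <- 2 * E0 - 0.2
  # state matrix: rows z, s, f, v, q; columns regions
  st <- rbind(z = c(0, 0), s = c(0, 0), f = c(1, 1), v = c(1, 1), q = c(1, 1))
  dfun <- function(st, Aeff, cu) {
    f <- pmax(st["f", ], 1e-6); v <- pmax(st["v", ], 1e-6)
    q <- pmax(st["q", ], 1e-6)
    fout <- v^(1 / alpha)
    E <- 1 - (1 - E0)^(1 / f)
    rbind(z = as.numeric(Aeff %*% st["z", ] + cu),
          s = st["z", ] - kappa * st["s", ] - gam * (f - 1),
          f = st["s", ],
          v = (f - fout) / tau,
          q = (f * E / E0 - fout * q / v) / tau)
  }
  bold <- matrix(0, nt, 2)
  for (t in seq_len(nt)) {
    um <- inputs$u_mod[t, ]; ud <- inputs$u_drive[t, ]
    Aeff <- m$A + um[1] * m$B$all + um[2] * m$B$later
    cu <- as.numeric(m$C %*% ud)
    d1 <- dfun(st, Aeff, cu)
    d2 <- dfun(st + dt / 2 * d1, Aeff, cu)
    d3 <- dfun(st + dt / 2 * d2, Aeff, cu)
    d4 <- dfun(st + dt * d3, Aeff, cu)
    st <- st + dt / 6 * (d1 + 2 * d2 + 2 * d3 + d4)
    v <- pmax(st["v", ], 1e-6); q <- pmax(st["q", ], 1e-6)
    bold[t, ] <- V0 * (k1 * (1 - q) + k2 * (1 - q / v) + k3 * (1 - v)) * 100
  }
  y <- bold[inputs$sample_idx, , drop = FALSE]
  colnames(y) <- c("d", "v")
  y
}

#' Invert a DCM by iterated Gauss-Newton under the Laplace approximation
#'
#' Gaussian priors on the parameters combine with a Gaussian observation
#' model (per-region noise precision, updated by maximum likelihood between
#' Gauss-Newton steps) to yield a Gaussian posterior over the coupling,
#' modulation and driving-input parameters, plus a free-energy approximation
#' to the log model evidence (accuracy minus complexity). Data and model
#' prediction are mean-centered per region, absorbing baseline offsets.
#'
#' @param bold Matrix (volumes x 2) of observed BOLD, columns `d`, `v`.
#' @param spec A `dcm_spec`.
#' @param inputs A `dcm_inputs` object.
#' @param max_iter Maximum Gauss-Newton iterations.
#' @param tol Convergence tolerance on the parameter update norm.
#' @param constants Hemodynamic constants.
#' @return List of class `dcm_posterior`: `mean` (named), `cov`,
#'   `free_energy`, `prob_positive` (P(parameter > 0) from the Gaussian
#'   marginals), `lambda` (per-region noise precisions), `converged`,
#'   `iterations`, `spec`.
#' @export
dcm_invert <- function(bold, spec, inputs, max_iter = 32L, tol = 1e-3,
                       constants = dcm_hemo_constants()) {
  bold <- as.matrix(bold)
  if (ncol(bold) != 2L) stop("expected a two-region BOLD matrix")
  if (nrow(bold) != inputs$volumes) stop("BOLD rows must equal input volumes")
  n <- nrow(bold)
  yd <- sweep(bold, 2, colMeans(bold))
  p <- length(spec$par_names)
  mu0 <- spec$prior_mean
  P0 <- diag(1 / spec$prior_var, p)
  theta <- mu0
  lambda <- 1 / pmax(apply(yd, 2, stats::var), 1e-8)
  predict_centered <- function(th) {
    g <- dcm_forward(th, spec, inputs, constants)
    sweep(g, 2, colMeans(g))
  }
  objective <- function(resid, th, lam) {
    -0.5 * sum(lam * colSums(resid^2)) + 0.5 * n * sum(log(lam)) -
      0.5 * sum((th - mu0)^2 / spec$prior_var)
  }
  g0 <- predict_centered(theta)
  resid <- yd - g0
  obj <- objective(resid, theta, lambda)
  converged <- FALSE
  iter <- 0L
  Sigma_p <- solve(P0)
  h <- 1e-3
  for (iter in seq_len(max_iter)) {
    J <- matrix(0, 2L * n, p)
    for (j in seq_len(p)) {
      th_j <- theta
      th_j[j] <- th_j[j] + h
      J[, j] <- as.numeric(predict_centered(th_j) - g0) / h
    }
    w <- rep(lambda, each = n)
    rvec <- as.numeric(resid)
    H <- crossprod(J, J * w) + P0
    Sigma_p <- tryCatch(solve(H), error = function(e) pseudo_inverse(H))
    grad <- crossprod(J, w * rvec) - P0 %*% (theta - mu0)
    delta <- as.numeric(Sigma_p %*% grad)
    step <- 1
    improved <- FALSE
    for (half in 1:8) {
      th_new <- theta + step * delta
      g_new <- tryCatch(predict_centered(th_new), error = function(e) NULL)
      if (!is.null(g_new)) {
        resid_new <- yd - g_new
        obj_new <- objective(resid_new, th_new, lambda)
        if (is.finite(obj_new) && obj_new > obj - 1e-12) {
          theta <- th_new; g0 <- g_new; resid <- resid_new; obj <- obj_new
          improved <- TRUE
          break
        }
      }
      step <- step / 2
    }
    lambda <- n / pmax(colSums(resid^2), 1e-12)
    obj <- objective(resid, theta, lambda)
    if (!improved || max(abs(step * delta)) < tol) {
      converged <- improved || max(abs(delta)) < tol * 10
      break
    }
  }
  # Laplace free energy: log joint at the mode + Gaussian volume correction
  log_lik <- -0.5 * sum(lambda * colSums(resid^2)) +
    0.5 * n * sum(log(lambda / (2 * pi)))
  log_prior <- -0.5 * sum((theta - mu0)^2 / spec$prior_var) -
    0.5 * sum(log(2 * pi * spec$prior_var))
  free_energy <- log_lik + log_prior +
    0.5 * determinant(Sigma_p, logarithm = TRUE)$modulus +
    0.5 * p * log(2 * pi)
  sd_post <- sqrt(pmax(diag(Sigma_p), 0))
  structure(list(mean = theta,
                 cov = (Sigma_p + t(Sigma_p)) / 2,
                 free_energy = as.numeric(free_energy),
                 prob_positive = stats::setNames(
                   1 - stats::pnorm(0, theta, pmax(sd_post, 1e-12)),
                   spec$par_names),
                 lambda = lambda,
                 converged = converged,
                 iterations = iter,
                 spec = spec),
            class = "dcm_posterior")
}

# Moore-Penrose fallback for near-singular Gauss-Newton Hessians.
pseudo_inverse <- function(X, tol = 1e-10) {
  s <- svd(X)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' @export
print.dcm_posterior <- function(x, ...) {
  cat(sprintf("dcm_posterior: F = %.2f, %d parameters, %s in %d iterations\n",
              x$free_energy, length(x$mean),
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}
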