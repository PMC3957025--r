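test_that("neural dynamics vanish with zero parameters and check dimensions", {
  A <- matrix(0, 2, 2); B <- list(matrix(0, 2, 2)); C <- matrix(0, 2, 1)
  expect_equal(neural_dynamics(c(1, -2), A, B, C, 1, 5), c(0, 0))
  expect_error(neural_dynamics(c(1, 2), A, B, C, c(1, 1), 5), "modulatory")
  expect_error(neural_dynamics(c(1, 2, 3), A, B, C, 1, 5), "mismatch")
})

test_that("a single self-coupled region decays as exp(-t)", {
  # dz/dt = -z, z0 = 1: RK4 at dt = 0.01 against the closed form
  A <- matrix(-1, 1, 1); B <- list(matrix(0, 1, 1)); C <- matrix(0, 1, 1)
  z <- 1; dt <- 0.01
  for (i in 1:200) {
    d1 <- neural_dynamics(z, A, B, C, 0, 0)
    d2 <- neural_dynamics(z + dt / 2 * d1, A, B, C, 0, 0)
    d3 <- neural_dynamics(z + dt / 2 * d2, A, B, C, 0, 0)
    d4 <- neural_dynamics(z + dt * d3, A, B, C, 0, 0)
    z <- z + dt / 6 * (d1 + 2 * d2 + 2 * d3 + d4)
  }
  expect_equal(z, exp(-2), tolerance = 1e-9)
})

test_that("compiled forward model matches the R reference exactly", {
  beh <- synth_behavior()
  inputs <- synth_inputs(beh, n_vol = 40)
  theta <- tdconnect:::ground_truth_means()
  spec <- dcm_spec(1)
  y_cpp <- dcm_forward(theta, spec, inputs)
  y_r <- tdconnect:::dcm_forward_r(theta, spec, inputs)
  expect_equal(y_cpp, y_r, tolerance = 1e-12)
  # deterministic
  expect_identical(y_cpp, dcm_forward(theta, spec, inputs))
})

test_that("zero parameters and inputs give flat baseline BOLD", {
  beh <- synth_behavior()
  inputs <- synth_inputs(beh, n_vol = 40)
  spec <- dcm_spec(1)
  theta0 <- stats::setNames(rep(0, length(spec$par_names)), spec$par_names)
  y <- dcm_forward(theta0, spec, inputs)
  expect_lt(max(abs(y)), 1e-10)
})

test_that("hemodynamics: flat input, impulse peak latency, step convergence", {
  flat <- hemodynamics(matrix(0, 100, 2), 0.1)
  expect_lt(max(abs(flat)), 1e-12)
  neu <- matrix(0, 200, 1); neu[11:20, 1] <- 1   # 1 s neural burst at t = 1 s
  b <- hemodynamics(neu, 0.1)
  peak_t <- (which.max(b) - 11) * 0.1
  expect_gt(peak_t, 3); expect_lt(peak_t, 8)
  expect_lt(min(b[which.max(b):200]), 0)         # undershoot after the peak
  # halving the integration step barely changes the solution
  neu2 <- matrix(0, 400, 1); neu2[21:40, 1] <- 1
  b2 <- hemodynamics(neu2, 0.05)
  rms <- sqrt(mean((b2[seq(2, 400, by = 2)] - b)^2))
  expect_lt(rms, 1e-4)
})

test_that("modulation acts only while its condition input is active", {
  beh <- synth_behavior()
  inputs <- synth_inputs(beh, n_vol = 60)
  spec <- dcm_spec(1)
  theta <- c(drive.accept_to_d = 0.5)
  theta_mod <- c(theta, all.d_to_v = 0.4)
  y0 <- dcm_forward(theta, spec, inputs)
  y1 <- dcm_forward(theta_mod, spec, inputs)
  expect_gt(max(abs(y1[, "v"] - y0[, "v"])), 1e-4)   # transfer opens d -> v
  # with the condition stream silenced the modulation is inert
  inputs_off <- inputs
  inputs_off$u_mod[, "all"] <- 0
  expect_equal(dcm_forward(theta_mod, spec, inputs_off),
               dcm_forward(theta, spec, inputs_off), tolerance = 1e-12)
})

test_that("doubling a driving gain increases the driven region's response", {
  beh <- synth_behavior()
  inputs <- synth_inputs(beh, n_vol = 60)
  spec <- dcm_spec(1)
  y1 <- dcm_forward(c(drive.accept_to_d = 0.3), spec, inputs)
  y2 <- dcm_forward(c(drive.accept_to_d = 0.6), spec, inputs)
  expect_gt(max(abs(y2[, "d"])), max(abs(y1[, "d"])))
})

test_that("inversion is self-consistent and returns a valid Gaussian posterior", {
  beh <- synth_behavior()
  inputs <- synth_inputs(beh, n_vol = 150)
  spec <- dcm_spec(1)
  theta <- tdconnect:::ground_truth_means()
  y <- dcm_forward(theta, spec, inputs)
  set.seed(31)
  yobs <- y + matrix(rnorm(length(y), 0, 0.3), ncol = 2)
  post <- dcm_invert(yobs, spec, inputs)
  expect_true(post$converged)
  ev <- eigen(post$cov, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-10))                       # PSD
  expect_true(is.finite(post$free_energy))
  # P(theta > 0) > 0.5 exactly when the posterior mean is positive
  expect_equal(unname(post$prob_positive > 0.5), unname(post$mean > 0))
  # strong drives recovered with the right sign
  expect_gt(post$mean["drive.value_to_v"], 0)
  expect_gt(post$mean["drive.accept_to_d"], 0)
  # the matched input placement beats a swapped one in free energy
  post_swap <- dcm_invert(yobs, dcm_spec(4), inputs)
  expect_gt(post$free_energy, post_swap$free_energy)
})

test_that("inversion is invariant to relabeling the two regions", {
  beh <- synth_behavior()
  inputs <- synth_inputs(beh, n_vol = 120)
  theta <- tdconnect:::ground_truth_means()
  y <- dcm_forward(theta, dcm_spec(1), inputs)
  set.seed(17)
  yobs <- y + matrix(rnorm(length(y), 0, 0.3), ncol = 2)
  p1 <- dcm_invert(yobs, dcm_spec(1), inputs)
  # family 4 with swapped data columns is the same model with regions renamed
  p4 <- dcm_invert(yobs[, c(2, 1)], dcm_spec(4), inputs)
  expect_equal(p4$free_energy, p1$free_energy, tolerance = 1e-6)
  relabel <- c(fixed.v_to_d = "fixed.d_to_v", fixed.d_to_v = "fixed.v_to_d",
               all.v_to_d = "all.d_to_v", all.d_to_v = "all.v_to_d",
               all.v_self = "all.d_self", all.d_self = "all.v_self",
               later.v_to_d = "later.d_to_v", later.d_to_v = "later.v_to_d",
               later.v_self = "later.d_self", later.d_self = "later.v_self",
               drive.value_to_d = "drive.value_to_v",
               drive.accept_to_v = "drive.accept_to_d")
  expect_equal(unname(p4$mean[names(relabel)[names(relabel) %in% names(p4$mean)]]),
               unname(p1$mean[relabel[names(relabel) %in% names(p4$mean)]]),
               tolerance = 1e-6)
})

test_that("freeing an unsupported parameter costs free energy; a real one pays", {
  beh <- synth_behavior()
  inputs <- synth_inputs(beh, n_vol = 150)
  full <- dcm_spec(1)
  reduced <- dcm_spec(1, mod_on = c(later.d_to_v = FALSE, later.v_to_d = FALSE,
                                    all.v_to_d = FALSE))
  # data generated without those modulations: the reduced model should win
  theta_null <- tdconnect:::ground_truth_means()
  theta_null[c("later.d_to_v", "later.v_to_d", "all.v_to_d")] <- 0
  y <- dcm_forward(theta_null, full, inputs)
  set.seed(42)
  yobs <- y + matrix(rnorm(length(y), 0, 0.3), ncol = 2)
  f_full <- dcm_invert(yobs, full, inputs)$free_energy
  f_red <- dcm_invert(yobs, reduced, inputs)$free_energy
  expect_gt(f_red, f_full)
  # data generated with a strong later d -> v modulation: freeing it pays
  theta_eff <- theta_null
  theta_eff["later.d_to_v"] <- 0.5
  y2 <- dcm_forward(theta_eff, full, inputs)
  set.seed(43)
  yobs2 <- y2 + matrix(rnorm(length(y2), 0, 0.3), ncol = 2)
  with_later <- dcm_spec(1, mod_on = c(later.v_to_d = FALSE,
                                       all.v_to_d = FALSE))
  f_with <- dcm_invert(yobs2, with_later, inputs)$free_energy
  f_without <- dcm_invert(yobs2, reduced, inputs)$free_energy
  expect_gt(f_with, f_without)
})

test_that("planted modulation is covered by the 90% interval (reduced scale)", {
  beh <- synth_behavior()
  inputs <- synth_inputs(beh)
  spec <- dcm_spec(1)
  theta <- tdconnect:::ground_truth_means()
  theta["later.d_to_v"] <- 0.3
  y0 <- dcm_forward(theta, spec, inputs)
  set.seed(7)
  cover <- vapply(1:10, function(i) {
    yobs <- y0 + cbind(tdconnect:::ar1_noise(nrow(y0), 0.35, 0.2),
                       tdconnect:::ar1_noise(nrow(y0), 0.35, 0.2))
    post <- dcm_invert(yobs, spec, inputs)
    j <- match("later.d_to_v", names(post$mean))
    abs(post$mean[j] - 0.3) <= qnorm(0.95) * sqrt(post$cov[j, j])
  }, logical(1))
  expect_gte(sum(cover), 7L)
})
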