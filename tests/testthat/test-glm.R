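test_that("canonical HRF has the expected double-gamma shape", {
  tg <- seq(0, 32, by = 0.01)
  h <- hrf(tg)
  expect_equal(h[1], 0)
  expect_equal(max(h), 1)                       # unit peak normalization
  peak_t <- tg[which.max(h)]
  expect_gt(peak_t, 4); expect_lt(peak_t, 7)
  # undershoot present and later than the peak
  expect_lt(min(h), 0)
  expect_gt(tg[which.min(h)], peak_t)
  expect_equal(hrf(c(-1, 40)), c(0, 0))
})

test_that("convolving an impulse with the kernel reproduces the kernel", {
  dt <- 0.1
  n_micro <- 400L
  u <- numeric(n_micro); u[1] <- 1 / dt        # unit-area impulse
  conv <- tdconnect:::convolve_downsample(u, dt, seq_len(n_micro))
  kern <- hrf(seq(0, by = dt, length.out = n_micro))
  expect_equal(conv, kern, tolerance = 1e-8)
})

make_design <- function(beh, values, volumes = 120) {
  sel <- beh$trials$onset + 4 < volumes * 2.5
  build_design(beh$trials[sel, , drop = FALSE], values[sel], volumes, 2.5)
}

test_that("design construction orthogonalizes Accept against value", {
  beh <- synth_behavior()
  dsv <- discounted_value(beh$trials$amount, beh$trials$delay, beh$k)
  des <- make_design(beh, dsv)
  expect_lt(abs(sum(des$X[, "value"] * des$X[, "accept"])), 1e-8)
  # value recoding that only flips sign preserves the column norm
  des2 <- make_design(beh, -dsv)
  expect_equal(sum(des2$X[, "value"]^2), sum(des$X[, "value"]^2),
               tolerance = 1e-10)
})

test_that("degenerate designs are flagged as rank deficient", {
  beh <- synth_behavior()
  tr <- beh$trials
  tr$choice[tr$choice != "missed"] <- "accept"   # Accept constant at 1
  sel <- tr$onset + 4 < 120 * 2.5
  expect_error(build_design(tr[sel, ], rep(1, sum(sel)), 120, 2.5),
               "rank|collinear")
})

test_that("noiseless data are recovered exactly and nonfinite data rejected", {
  beh <- synth_behavior()
  dsv <- discounted_value(beh$trials$amount, beh$trials$delay, beh$k)
  des <- make_design(beh, dsv)
  beta <- seq_len(ncol(des$X)) / 10
  y <- as.numeric(des$X %*% beta)
  g <- fit_glm(y, des)
  expect_equal(unname(g$beta), beta, tolerance = 1e-8)
  expect_error(fit_glm(c(y[-1], NaN), des), "finite")
})

test_that("sign-flipping the value modulator preserves |t| and model evidence", {
  beh <- synth_behavior()
  dsv <- discounted_value(beh$trials$amount, beh$trials$delay, beh$k)
  des_pos <- make_design(beh, dsv)
  des_neg <- make_design(beh, 25 - dsv)          # the NG recoding
  set.seed(14)
  y <- 0.8 * des_pos$X[, "value"] + 0.4 * des_pos$X[, "accept"] + rnorm(120)
  g1 <- fit_glm(y, des_pos)
  g2 <- fit_glm(y, des_neg)
  expect_equal(g2$contrasts$value$t, -g1$contrasts$value$t, tolerance = 1e-8)
  expect_equal(abs(g2$contrasts$value$t), abs(g1$contrasts$value$t),
               tolerance = 1e-8)
  expect_equal(g2$log_evidence, g1$log_evidence, tolerance = 1e-8)
  # positive rescaling of the modulator also leaves the evidence unchanged
  des_scaled <- make_design(beh, 10 * dsv)
  g3 <- fit_glm(y, des_scaled)
  expect_equal(g3$log_evidence, g1$log_evidence, tolerance = 1e-8)
  expect_equal(abs(g3$contrasts$value$t), abs(g1$contrasts$value$t),
               tolerance = 1e-8)
})

test_that("AR(1) prewhitening removes residual lag-1 autocorrelation", {
  beh <- synth_behavior()
  dsv <- discounted_value(beh$trials$amount, beh$trials$delay, beh$k)
  des <- make_design(beh, dsv, volumes = 300)
  rho_true <- 0.4
  set.seed(4)
  y <- as.numeric(stats::arima.sim(list(ar = rho_true), nrow(des$X)))
  g <- fit_glm(y, des)
  expect_lt(abs(g$rho - rho_true), 0.1)
  # whiten with the estimated coefficient and check the residuals
  W <- function(v) c(sqrt(1 - g$rho^2) * v[1], v[-1] - g$rho * v[-length(v)])
  Xw <- apply(des$X, 2, W)
  rw <- stats::lm.fit(Xw, W(y))$residuals
  expect_lt(abs(cor(rw[-1], rw[-length(rw)])), 0.08)
})

test_that("group t-test matches a hand-computed fixture and flags degeneracy", {
  vals <- c(0.8, 1.2, -0.1, 0.5, 0.9, 1.4, 0.2, 0.7, 1.1, 0.3)
  gt <- group_ttest(vals)
  # textbook one-sample t: mean / (sd / sqrt(n))
  t_hand <- mean(vals) / (sd(vals) / sqrt(10))
  expect_equal(gt$t, t_hand, tolerance = 1e-12)
  expect_equal(gt$df, 9)
  sym <- c(-2, -1, 1, 2)
  gs <- group_ttest(sym)
  expect_equal(gs$t, 0)
  expect_equal(gs$p, 1)
  gi <- group_ttest(rep(3, 5))
  expect_true(gi$infinite)
  expect_equal(gi$t, Inf)
  expect_error(group_ttest(rep(0, 5)), "undefined")
  expect_error(group_ttest(c(1, 2)), "3 subjects")
})

test_that("full-vs-reduced comparison detects a planted value signal", {
  beh <- synth_behavior()
  dsv <- discounted_value(beh$trials$amount, beh$trials$delay, beh$k)
  des <- make_design(beh, dsv, volumes = 150)
  n_sub <- 10
  set.seed(20)
  with_signal <- lapply(1:n_sub, function(i)
    1.0 * des$X[, "value"] + rnorm(nrow(des$X)))
  without <- lapply(1:n_sub, function(i) rnorm(nrow(des$X)))
  designs <- rep(list(des), n_sub)
  cmp1 <- compare_full_vs_reduced(with_signal, designs, seed = 2,
                                  n_draws = 1e4)
  expect_gt(cmp1$exceedance_full, 0.9)
  cmp0 <- compare_full_vs_reduced(without, designs, seed = 2, n_draws = 1e4)
  expect_lt(cmp0$exceedance_full, 0.6)
})

test_that("null Accept contrast keeps its nominal size (reduced scale)", {
  beh <- synth_behavior()
  dsv <- discounted_value(beh$trials$amount, beh$trials$delay, beh$k)
  des <- make_design(beh, dsv, volumes = 150)
  set.seed(9)
  ps <- replicate(400, fit_glm(rnorm(nrow(des$X)), des)$contrasts$accept$p)
  expect_gt(mean(ps < 0.05), 0.02)
  expect_lt(mean(ps < 0.05), 0.09)
})
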