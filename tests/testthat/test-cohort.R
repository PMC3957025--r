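test_that("generated data dimensions follow the cohort configuration", {
  cfg <- cohort_config(seed = 21, n_subjects = 2L, runs_per_subject = 2L)
  co <- simulate_cohort(cfg)
  expect_length(co$subjects, 2L)
  for (s in co$subjects) {
    expect_length(s$bold, 2L)
    for (y in s$bold) expect_equal(dim(y), c(323L, 2L))
    expect_equal(nrow(s$trials), 216L)
  }
})

test_that("cohort generation is bit-identical under a fixed seed", {
  cfg <- cohort_config(seed = 33, n_subjects = 2L, runs_per_subject = 1L)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$subjects[[1]]$bold[[1]], b$subjects[[1]]$bold[[1]])
  expect_identical(a$ground_truth$planted_later_d_to_v,
                   b$ground_truth$planted_later_d_to_v)
  c2 <- simulate_cohort(cohort_config(seed = 34, n_subjects = 2L,
                                      runs_per_subject = 1L))
  expect_false(identical(a$subjects[[1]]$bold[[1]],
                         c2$subjects[[1]]$bold[[1]]))
})

test_that("simulated choice frequencies obey the softmax law (binomial check)", {
  cfg <- cohort_config(seed = 99)
  # ~50 sessions x 216 trials > 10,000 simulated choices at fixed (k, b)
  trials <- do.call(rbind, lapply(1:50, function(i)
    simulate_subject_behavior(cfg, i, k = 0.02, b = 0.5)$trials))
  trials <- trials[trials$choice != "missed", ]
  p <- p_accept(discounted_value(trials$amount, trials$delay, 0.02), 0.5)
  bins <- cut(p, breaks = seq(0, 1, 0.1), include.lowest = TRUE)
  for (lev in levels(bins)) {
    sel <- bins == lev
    if (sum(sel) < 50) next
    emp <- mean(trials$choice[sel] == "accept")
    expected <- mean(p[sel])
    se <- sqrt(expected * (1 - expected) / sum(sel))
    expect_lt(abs(emp - expected), 4 * se + 1e-12)
  }
})

test_that("realized sessions respect the response window and miss rate", {
  cfg <- cohort_config(seed = 12)
  beh <- simulate_subject_behavior(cfg, 4)
  resp <- beh$trials$choice != "missed"
  expect_true(all(beh$trials$rt[resp] <= 3))
  expect_true(all(is.na(beh$trials$rt[!resp])))
  expect_lt(mean(!resp), 0.10)
  # re-timed sessions stay inside the scanned run
  for (r in 1:2) {
    last <- max(beh$trials$onset[beh$trials$run == r] +
                  beh$trials$duration[beh$trials$run == r])
    expect_lt(last, 323 * 2.5)
  }
})

test_that("RT generator reproduces the group-by-choice interaction sign", {
  cfg <- cohort_config(seed = 8)
  wg <- simulate_subject_behavior(cfg, 1, k = 0.004, b = 1)  # patient
  ng <- simulate_subject_behavior(cfg, 2, k = 0.02, b = 1)   # impatient
  expect_equal(wg$group, "WG")
  expect_equal(ng$group, "NG")
  m <- function(beh, ch) mean(beh$trials$rt[beh$trials$choice == ch],
                              na.rm = TRUE)
  expect_lt(m(wg, "accept"), m(wg, "reject"))
  expect_gt(m(ng, "accept"), m(ng, "reject"))
})

test_that("null cohorts plant no association; strong effects hit the noise ceiling", {
  # aggregate over seeds: the planted parameter under effect_size = 0
  r0 <- vapply(1:30, function(s) {
    co <- simulate_cohort(cohort_config(seed = 5000 + s, n_subjects = 8L,
                                        runs_per_subject = 1L,
                                        effect_size = 0))
    cor(co$ground_truth$planted_later_d_to_v, log(co$ground_truth$k))
  }, numeric(1))
  expect_lt(abs(mean(r0)), 0.12)
  # large effect: sample correlation approaches the attenuation ceiling
  s_eff <- 0.4; sigma <- 0.05
  ceiling_r <- s_eff / sqrt(s_eff^2 + sigma^2)
  r1 <- vapply(1:10, function(s) {
    co <- simulate_cohort(cohort_config(seed = 6000 + s, n_subjects = 8L,
                                        runs_per_subject = 1L,
                                        effect_size = s_eff,
                                        effect_noise_sd = sigma))
    cor(co$ground_truth$planted_later_d_to_v, -log(co$ground_truth$k))
  }, numeric(1))
  expect_lt(abs(mean(r1) - ceiling_r), 0.08)
})

test_that("estimation never reads the ground truth", {
  co <- simulate_cohort(cohort_config(seed = 71, n_subjects = 4L,
                                      runs_per_subject = 1L))
  blinded <- co
  blinded$ground_truth <- NULL
  ft_full <- extract_features(co)
  ft_blind <- extract_features(blinded)
  expect_identical(ft_full$features, ft_blind$features)
  expect_identical(ft_full$target, ft_blind$target)
  # inputs untouched by the estimation pass
  expect_identical(co$subjects, blinded$subjects)
})

test_that("cohort round-trips through the plain-text on-disk format", {
  co <- simulate_cohort(cohort_config(seed = 77, n_subjects = 2L,
                                      runs_per_subject = 1L))
  dir <- file.path(tempdir(), "cohort_rt")
  manifest <- write_cohort(co, dir)
  expect_true(all(file.exists(file.path(dir, manifest$file))))
  back <- read_cohort(dir)
  expect_equal(back$subjects[[1]]$trials$amount, co$subjects[[1]]$trials$amount)
  expect_equal(back$subjects[[1]]$bold[[1]][, 1], co$subjects[[1]]$bold[[1]][, 1],
               tolerance = 1e-6)
  expect_equal(back$ground_truth$k, co$ground_truth$k, tolerance = 1e-8)
  unlink(dir, recursive = TRUE)
})
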