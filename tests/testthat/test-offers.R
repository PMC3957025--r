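test_that("packaged offer grid is the 18 x 6 design with 108 unique offers", {
  grid <- load_offer_grid()
  expect_s3_class(grid, "offer_grid")
  expect_equal(nrow(grid), 18L)
  pairs <- offer_pairs(grid)
  expect_equal(nrow(pairs), 108L)
  expect_equal(nrow(unique(pairs)), 108L)
  expect_equal(range(pairs$amount), c(25, 54))
  expect_equal(range(pairs$delay), c(7, 200))
})

test_that("malformed offer grids are rejected", {
  grid <- load_offer_grid()
  tmp <- tempfile(fileext = ".tsv")
  utils::write.table(grid[-1, ], tmp, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  expect_error(load_offer_grid(tmp), "18")
  bad <- grid
  bad$amount3[2] <- 27.5
  utils::write.table(bad, tmp, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(load_offer_grid(tmp), "integer")
  bad <- grid
  bad$delay[5] <- 5   # below the design's minimum delay
  utils::write.table(bad, tmp, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(load_offer_grid(tmp))
})

test_that("build_session lays out 216 trials, each offer twice, ITIs in [2, 6]", {
  grid <- load_offer_grid()
  tr <- build_session(grid, seed = 7)
  expect_equal(nrow(tr), 216L)
  expect_equal(as.vector(table(tr$run)), c(108L, 108L))
  counts <- table(paste(tr$delay, tr$amount))
  expect_true(all(counts == 2L))
  # inter-trial intervals recovered from the onset layout (3 s window + 250 ms)
  for (r in 1:2) {
    on <- tr$onset[tr$run == r]
    iti <- diff(c(0, on)) - c(0, rep(3.25, length(on) - 1L))
    expect_true(all(iti >= 2 & iti <= 6))
  }
  expect_identical(build_session(grid, seed = 7), tr)
  expect_false(identical(build_session(grid, seed = 8)$amount, tr$amount))
})

test_that("discounted_value follows the hyperbolic form and its limits", {
  expect_equal(discounted_value(35, 200, 0), 35)
  expect_equal(discounted_value(30, 10, 0.1), 15)
  expect_equal(discounted_value(54, 200, 0.01), 18)
  expect_error(discounted_value(30, 10, -0.1), "non-negative")
  ks <- seq(0, 1, length.out = 50)
  expect_true(all(diff(discounted_value(40, 100, ks)) < 0))
  ds <- seq(7, 200, length.out = 50)
  expect_true(all(diff(discounted_value(40, ds, 0.05)) < 0))
})

test_that("p_accept is a logistic in dSV anchored at the $25 reference", {
  for (b in c(0, 0.1, 1, 10)) expect_equal(p_accept(25, b), 0.5)
  expect_equal(p_accept(c(10, 30, 50), 0), rep(0.5, 3))
  expect_gt(p_accept(35, 50), 1 - 1e-10)
  expect_error(p_accept(30, -1), "non-negative")
  dsv <- seq(5, 50, length.out = 40)
  expect_true(all(diff(p_accept(dsv, 0.5)) > 0))
})

test_that("likelihood agrees with a direct Bernoulli-product evaluation", {
  grid <- load_offer_grid()
  pairs <- offer_pairs(grid)
  set.seed(11)
  accepted <- runif(nrow(pairs)) < 0.5
  for (i in 1:20) {
    # b capped where the explicit product is still numerically representable
    k <- runif(1, 1e-4, 0.3); b <- runif(1, 0.01, 0.8)
    # independent oracle: explicit probability product
    p <- 1 / (1 + exp(b * (25 - pairs$amount / (1 + k * pairs$delay))))
    oracle <- sum(log(ifelse(accepted, p, 1 - p)))
    expect_equal(tdconnect:::choice_loglik(k, b, pairs$amount, pairs$delay,
                                           accepted),
                 oracle, tolerance = 1e-10)
  }
})

test_that("fit_discounting recovers simulated parameters and beats a grid search", {
  grid <- load_offer_grid()
  pairs <- offer_pairs(grid)
  set.seed(3)
  idx <- sample(nrow(pairs), 2000, replace = TRUE)
  trials <- data.frame(amount = pairs$amount[idx], delay = pairs$delay[idx])
  p <- p_accept(discounted_value(trials$amount, trials$delay, 0.02), 0.5)
  trials$choice <- ifelse(runif(2000) < p, "accept", "reject")
  fit <- fit_discounting(trials)
  expect_true(fit$converged)
  expect_lt(abs(fit$k - 0.02) / 0.02, 0.2)
  # dense grid-search oracle: the optimizer must match or beat the grid
  gl <- expand.grid(logk = seq(log(1e-4), log(0.5), length.out = 60),
                    logb = seq(log(0.01), log(5), length.out = 40))
  acc <- trials$choice == "accept"
  gll <- mapply(function(lk, lb)
    tdconnect:::choice_loglik(exp(lk), exp(lb), trials$amount, trials$delay,
                              acc),
    gl$logk, gl$logb)
  expect_gte(fit$loglik, max(gll) - 1e-6)
  # optimality against a fixed alternative
  expect_gte(fit$loglik,
             tdconnect:::choice_loglik(1, 1, trials$amount, trials$delay, acc))
})

test_that("degenerate choice data yield boundary flags, not errors", {
  grid <- load_offer_grid()
  pairs <- offer_pairs(grid)
  all_acc <- data.frame(amount = pairs$amount, delay = pairs$delay,
                        choice = "accept")
  fit <- fit_discounting(all_acc)
  expect_true(fit$boundary)
  # b = 0 data: choices carry no information about k
  set.seed(5)
  flat <- data.frame(amount = pairs$amount, delay = pairs$delay,
                     choice = ifelse(runif(nrow(pairs)) < 0.5, "accept",
                                     "reject"))
  fit2 <- fit_discounting(flat)
  expect_true(fit2$boundary)
})

test_that("group assignment uses the strict majority rule with NG ties", {
  mk <- function(acc, rej, miss = 0)
    data.frame(choice = c(rep("accept", acc), rep("reject", rej),
                          rep("missed", miss)))
  expect_equal(assign_group(mk(60, 40)), "WG")
  expect_equal(assign_group(mk(40, 60)), "NG")
  expect_equal(assign_group(mk(50, 50)), "NG")
  expect_equal(assign_group(mk(51, 49, 10)), "WG")  # missed excluded
  expect_error(assign_group(mk(0, 0, 5)), "responded")
})

test_that("rdSV recoding flips sign by group and vanishes at the reference", {
  tr <- data.frame(amount = c(30, 25, 40), delay = c(0, 0, 0))
  fit <- list(k = 0.05)
  wg <- rdsv_series(tr, fit, "WG")
  ng <- rdsv_series(tr, fit, "NG")
  expect_equal(wg, c(5, 0, 15))
  expect_equal(ng, -wg)
})
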