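#' Hyperbolic discounted stimulus value
#'
#' The subjective value of receiving amount `A` after `D` days under
#' hyperbolic discounting with rate `k` (per day):
#' `dSV = A / (1 + k * D)`.
#'
#' @param amount Offer amount(s), currency units.
#' @param delay Delay(s) in days.
#' @param k Discount rate per day, `k >= 0`.
#' @return Discounted stimulus value(s), same length as the offers.
#' @export
discounted_value <- function(amount, delay, k) {
  if (any(k < 0)) stop("discount rate k must be non-negative")
  amount / (1 + k * delay)
}

#' Softmax probability of accepting the delayed option
#'
#' The delayed offer is chosen against a constant immediate reference
#' (default $25) with probability
#' `P(yes) = 1 / (1 + exp(b * (reference - dSV)))`,
#' where `b >= 0` sets the slope of the psychometric function.
#'
#' @param dsv Discounted stimulus value(s) of the delayed offer.
#' @param b Softmax slope, `b >= 0`.
#' @param reference Immediate reference amount (default 25).
#' @return Acceptance probability in (0, 1); exactly 0.5 at `dsv == reference`.
#' @export
p_accept <- function(dsv, b, reference = 25) {
  if (any(b < 0)) stop("softmax slope b must be non-negative")
  stats::plogis(b * (dsv - reference))
}

# Bernoulli log-likelihood of the responded choices given (k, b), computed on
# the log scale so extreme psychometric slopes do not underflow.
# Missed trials must already be excluded.
choice_loglik <- function(k, b, amount, delay, accepted, reference = 25) {
  eta <- b * (discounted_value(amount, delay, k) - reference)
  sum(stats::plogis(eta, log.p = TRUE)[accepted]) +
    sum(stats::plogis(eta, lower.tail = FALSE, log.p = TRUE)[!accepted])
}

#' Fit the hyperbolic discounting + softmax choice model by maximum likelihood
#'
#' Estimates the discount rate `k` and softmax slope `b` from binary
#' accept/reject choices by maximizing the Bernoulli likelihood under
#' [p_accept()] applied to [discounted_value()]. Missed trials are excluded.
#' The search runs in `(log k, log b)` with L-BFGS-B from a 3 x 3 grid of
#' starting points; this avoids positivity constraints and local optima.
#'
#' @param trials Trial data frame with columns `amount`, `delay`, `choice`
#'   (values `"accept"`, `"reject"`, `"missed"`).
#' @param reference Immediate reference amount (default 25).
#' @param k_bounds Search bounds for `k` per day; outside `[1e-6, 1]` the
#'   7--200 day design carries no information.
#' @param b_bounds Search bounds for the slope `b`.
#' @return List of class `discount_fit`: `k`, `b`, `loglik`, `converged`,
#'   `boundary` (TRUE when the optimum sits on a box bound or the likelihood
#'   is flat in `k`), and `n_trials` (responded trials used).
#' @export
fit_discounting <- function(trials, reference = 25,
                            k_bounds = c(1e-6, 1), b_bounds = c(1e-3, 100)) {
  resp <- trials[!is.na(trials$choice) & trials$choice != "missed", , drop = FALSE]
  if (nrow(resp) == 0L) stop("no responded trials to fit")
  accepted <- resp$choice == "accept"
  nll <- function(par) {
    -choice_loglik(exp(par[1]), exp(par[2]),
                   resp$amount, resp$delay, accepted, reference)
  }
  lo <- log(c(k_bounds[1], b_bounds[1]))
  hi <- log(c(k_bounds[2], b_bounds[2]))
  starts <- expand.grid(logk = log(c(1e-3, 1e-2, 1e-1)),
                        logb = log(c(0.05, 0.5, 5)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(as.numeric(starts[i, ]), nll, method = "L-BFGS-B",
                   lower = lo, upper = hi,
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimizer starts failed")
  k <- exp(best$par[1]); b <- exp(best$par[2])
  tol <- 1e-6
  on_bound <- (best$par[1] <= lo[1] + tol) || (best$par[1] >= hi[1] - tol) ||
    (best$par[2] <= lo[2] + tol) || (best$par[2] >= hi[2] - tol)
  # degenerate data (b ~ 0): the fit carries no real evidence over a
  # coin-flip choice rule, so k is unidentified
  ll_opt <- -best$value
  flat_k <- (ll_opt - nrow(resp) * log(0.5)) < 2
  structure(list(k = k, b = b, loglik = ll_opt,
                 converged = best$convergence == 0L,
                 boundary = on_bound || flat_k,
                 n_trials = nrow(resp)),
            class = "discount_fit")
}

#' @export
print.discount_fit <- function(x, ...) {
  cat(sprintf("discount_fit: k = %.4g /day, b = %.4g, logLik = %.2f (%s%s)\n",
              x$k, x$b, x$loglik,
              if (x$converged) "converged" else "NOT converged",
              if (x$boundary) ", boundary" else ""))
  invisible(x)
}

#' Assign a subject to the wait group (WG) or now group (NG)
#'
#' Subjects who accept the delayed option on strictly more than half of
#' their responded trials form the wait group; all others (including an
#' exact 50/50 tie) form the now group.
#'
#' @param trials Trial data frame with a `choice` column.
#' @param threshold Accept-fraction threshold (default 0.5, strict).
#' @return `"WG"` or `"NG"`.
#' @export
assign_group <- function(trials, threshold = 0.5) {
  resp <- trials$choice[!is.na(trials$choice) & trials$choice != "missed"]
  if (length(resp) == 0L) stop("no responded trials; cannot assign group")
  if (mean(resp == "accept") > threshold) "WG" else "NG"
}

#' Relative discounted stimulus value series
#'
#' Recodes each trial's dSV relative to the $25 reference, signed by the
#' subject's modal choice: `dSV - 25` for wait-group subjects and
#' `25 - dSV` for now-group subjects.
#'
#' @param trials Trial data frame with `amount` and `delay`.
#' @param fit A `discount_fit` (only `k` is used).
#' @param group `"WG"` or `"NG"`.
#' @param reference Immediate reference amount (default 25).
#' @return Numeric vector of per-trial rdSV values.
#' @export
rdsv_series <- function(trials, fit, group, reference = 25) {
  group <- match.arg(group, c("WG", "NG"))
  dsv <- discounted_value(trials$amount, trials$delay, fit$k)
  if (group == "WG") dsv - reference else reference - dsv
}
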