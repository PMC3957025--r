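#' Elastic-net linear regression by coordinate descent
#'
#' Minimizes `(1/2n) ||y - b0 - X b||^2 + lambda * (alpha ||b||_1 +
#' (1-alpha)/2 ||b||_2^2)`. Predictors are standardized internally (zero
#' mean, unit variance over the supplied rows) and coefficients returned on
#' the original scale; the intercept is unpenalized. Deterministic given the
#' inputs.
#'
#' @param X Predictor matrix (n x p).
#' @param y Response vector.
#' @param alpha Mixing parameter in \[0, 1\] (1 = lasso, 0 = ridge).
#' @param lambda Penalty level, `>= 0`.
#' @param tol Convergence tolerance on the coefficient updates.
#' @param max_iter Maximum full coordinate sweeps.
#' @return List of class `enet_fit`: `intercept`, `beta` (named), `lambda`,
#'   `alpha`, `objective` (penalized objective at the solution), `iterations`.
#' @export
elastic_net_fit <- function(X, y, alpha = 0.3, lambda = 0, tol = 1e-10,
                            max_iter = 10000L) {
  X <- as.matrix(X)
  if (any(!is.finite(X)) || any(!is.finite(y))) stop("non-finite inputs")
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (lambda < 0) stop("lambda must be non-negative")
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n)
  mx <- colMeans(X)
  sx <- sqrt(colMeans(sweep(X, 2, mx)^2))
  keep <- sx > 1e-12
  Z <- sweep(X[, keep, drop = FALSE], 2, mx[keep])
  Z <- sweep(Z, 2, sx[keep], `/`)
  my <- mean(y)
  yc <- y - my
  pk <- ncol(Z)
  cd <- enet_cd(Z, yc, alpha, lambda, numeric(pk), tol, max_iter)
  beta <- cd$beta
  it <- cd$iterations
  beta_orig <- numeric(p)
  beta_orig[keep] <- beta / sx[keep]
  intercept <- my - sum(mx[keep] * beta_orig[keep])
  obj <- sum((yc - if (pk) Z %*% beta else 0)^2) / (2 * n) +
    lambda * (alpha * sum(abs(beta)) + (1 - alpha) / 2 * sum(beta^2))
  structure(list(intercept = intercept,
                 beta = stats::setNames(beta_orig, colnames(X)),
                 beta_standardized = beta,
                 lambda = lambda, alpha = alpha,
                 objective = obj, iterations = it),
            class = "enet_fit")
}

#' @rdname elastic_net_fit
#' @param fit An `enet_fit`.
#' @param newdata Matrix of predictors to score.
#' @export
predict_enet <- function(fit, newdata) {
  as.numeric(fit$intercept + as.matrix(newdata) %*% fit$beta)
}

# Cyclic coordinate descent on standardized predictors (columns of Z have
# zero mean and unit variance with the 1/n convention; yc is centered).
enet_cd <- function(Z, yc, alpha, lambda, beta, tol, max_iter) {
  pk <- length(beta)
  r <- yc - if (pk) as.numeric(Z %*% beta) else 0
  n <- length(yc)
  it <- 0L
  if (pk > 0) {
    shrink <- 1 + lambda * (1 - alpha)
    thr <- lambda * alpha
    for (it in seq_len(max_iter)) {
      delta_max <- 0
      for (j in seq_len(pk)) {
        bj_old <- beta[j]
        rho <- sum(Z[, j] * r) / n + bj_old
        bj <- sign(rho) * max(abs(rho) - thr, 0) / shrink
        if (bj != bj_old) {
          r <- r - Z[, j] * (bj - bj_old)
          beta[j] <- bj
          delta_max <- max(delta_max, abs(bj - bj_old))
        }
      }
      if (delta_max < tol) break
    }
  }
  list(beta = beta, iterations = it)
}

# Log-spaced penalty path from the smallest lambda that zeroes all
# coefficients down by `ratio`.
enet_lambda_path <- function(X, y, alpha, n_lambda = 20L, ratio = 1e-2) {
  X <- as.matrix(X)
  mx <- colMeans(X); sx <- sqrt(colMeans(sweep(X, 2, mx)^2))
  keep <- sx > 1e-12
  Z <- sweep(sweep(X[, keep, drop = FALSE], 2, mx[keep]), 2, sx[keep], `/`)
  yc <- y - mean(y)
  lmax <- max(abs(crossprod(Z, yc)) / nrow(X)) / max(alpha, 1e-3)
  exp(seq(log(lmax), log(lmax * ratio), length.out = n_lambda))
}

# Seeded k-fold cross-validation over a lambda path; returns the lambda with
# the smallest mean squared prediction error.
cv_elastic_net <- function(X, y, alpha = 0.3, n_folds = 5L, seed = 1L,
                           lambdas = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(lambdas)) lambdas <- enet_lambda_path(X, y, alpha)
  rng <- local_rng(seed)
  folds <- sample(rep(seq_len(n_folds), length.out = n))
  restore_rng(rng)
  lambdas <- sort(lambdas, decreasing = TRUE)   # warm starts down the path
  err <- matrix(NA_real_, n_folds, length(lambdas))
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    if (sum(tr) < 2L || stats::sd(y[tr]) == 0) next
    Xtr <- X[tr, , drop = FALSE]
    mx <- colMeans(Xtr)
    sx <- sqrt(colMeans(sweep(Xtr, 2, mx)^2))
    keep <- sx > 1e-12
    Z <- sweep(sweep(Xtr[, keep, drop = FALSE], 2, mx[keep]), 2, sx[keep], `/`)
    yc <- y[tr] - mean(y[tr])
    Zte <- sweep(sweep(X[!tr, keep, drop = FALSE], 2, mx[keep]), 2,
                 sx[keep], `/`)
    beta <- numeric(ncol(Z))
    for (li in seq_along(lambdas)) {
      beta <- enet_cd(Z, yc, alpha, lambdas[li], beta, 1e-6, 2000L)$beta
      pred <- mean(y[tr]) + as.numeric(Zte %*% beta)
      err[f, li] <- mean((y[!tr] - pred)^2)
    }
  }
  mse <- colMeans(err, na.rm = TRUE)
  list(lambda = lambdas[which.min(mse)], lambdas = lambdas, mse = mse)
}
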