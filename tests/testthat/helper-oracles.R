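# Independent reference solvers used to validate the elastic net.

# Proximal-gradient (ISTA) solver on standardized data.
ista_enet <- function(Z, yc, alpha, lambda, n_iter = 20000L) {
  n <- nrow(Z); p <- ncol(Z)
  L <- max(eigen(crossprod(Z) / n, symmetric = TRUE,
                 only.values = TRUE)$values) + lambda * (1 - alpha)
  beta <- numeric(p)
  for (i in seq_len(n_iter)) {
    grad <- -crossprod(Z, yc - Z %*% beta) / n + lambda * (1 - alpha) * beta
    b <- beta - grad / L
    beta_new <- sign(b) * pmax(abs(b) - lambda * alpha / L, 0)
    if (max(abs(beta_new - beta)) < 1e-12) { beta <- beta_new; break }
    beta <- beta_new
  }
  beta
}

# The penalized objective both solvers minimize.
enet_objective <- function(Z, yc, beta, alpha, lambda) {
  sum((yc - Z %*% beta)^2) / (2 * nrow(Z)) +
    lambda * (alpha * sum(abs(beta)) + (1 - alpha) / 2 * sum(beta^2))
}
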