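# Shared fixtures and independent oracle implementations used across the
# test files. Oracles are deliberately written with different algorithms
# than the package code paths they check.

# tiny deterministic dataset: n samples, p CpGs, optional signal in column 1
toy_dataset <- function(n = 60, p = 4, effect = 0, seed = 42) {
  set.seed(seed)
  G <- matrix(stats::rbeta(n * p, 5, 5), n, p)
  eta <- effect * (G[, 1] - 0.5) * 4
  y <- stats::rbinom(n, 1, stats::plogis(eta))
  # guarantee both classes
  if (sum(y) < 2) y[1:2] <- 1L
  if (sum(1 - y) < 2) y[3:4] <- 0L
  list(G = G, y = y)
}

# independent Newton-Raphson logistic fit (textbook iteration, no glm.fit)
oracle_logistic <- function(Xd, y, iters = 60) {
  beta <- rep(0, ncol(Xd))
  for (i in seq_len(iters)) {
    eta <- drop(Xd %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- diag(as.vector(mu * (1 - mu)), nrow(Xd))
    beta <- beta + solve(t(Xd) %*% W %*% Xd, t(Xd) %*% (y - mu))
  }
  mu <- 1 / (1 + exp(-drop(Xd %*% beta)))
  list(beta = drop(beta), mu = mu,
       loglik = sum(y * log(mu) + (1 - y) * log(1 - mu)))
}

# closed-form inverse square root of a 2x2 SPD matrix:
# sqrt(S) = (S + sqrt(det) I) / sqrt(tr + 2 sqrt(det)), then invert
oracle_inv_sqrt_2x2 <- function(S) {
  sd2 <- sqrt(det(S))
  Sh <- (S + sd2 * diag(2)) / sqrt(sum(diag(S)) + 2 * sd2)
  solve(Sh)
}

# exchangeable beta marginals helper
same_marginals <- function(p, mean = 0.6, precision = 10) {
  replicate(p, beta_marginal(mean, precision), simplify = FALSE)
}
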