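# Independent oracles: every routine here reaches the target quantity by a
# different route than the package code (dense covariance algebra instead of
# the conditional AR recursion; explicit loops instead of vectorized scans).

# log density of y under N(mu, Sigma), via Cholesky of the dense covariance
mvn_logdens <- function(y, mu, Sigma) {
  R <- chol(Sigma)
  z <- backsolve(R, y - mu, transpose = TRUE)
  -0.5 * length(y) * log(2 * pi) - sum(log(diag(R))) - 0.5 * sum(z^2)
}

# dense AR(1) covariance: Sigma_ij = sigma_e^2 * rho^|i-j|
ar1_cov <- function(n, rho, sigma_eps) {
  sigma_e2 <- sigma_eps^2 / (1 - rho^2)
  sigma_e2 * rho^abs(outer(seq_len(n), seq_len(n), "-"))
}

# BUCP log-likelihood via the joint multivariate normal (stationary first
# observation), bypassing the conditional factorization entirely
dense_loglik <- function(y, beta1, beta2, rho, sigma_eps, tau) {
  n <- length(y)
  mu <- ifelse(seq_len(n) <= tau, beta1, beta2)
  mvn_logdens(y, mu, ar1_cov(n, rho, sigma_eps))
}

# brute-force change-point conditional by enumeration over the support
tau_conditional_enum <- function(y, beta1, beta2, rho, sigma_eps) {
  sup <- 3:(length(y) - 3)
  ll <- vapply(sup, function(k)
    dense_loglik(y, beta1, beta2, rho, sigma_eps, k), numeric(1))
  p <- exp(ll - max(ll))
  stats::setNames(p / sum(p), sup)
}

# exact change-point marginal with the intercepts integrated out under a
# fixed Normal(b0, 1/h0) prior, at known (rho, sigma_eps): for each k,
# y ~ N(Z b0, Sigma_AR + Z Z' / h0) with Z the two-phase design at k
tau_marginal_integrated <- function(y, rho, sigma_eps, b0, h0) {
  n <- length(y)
  sup <- 3:(n - 3)
  Sig <- ar1_cov(n, rho, sigma_eps)
  ll <- vapply(sup, function(k) {
    z1 <- as.numeric(seq_len(n) <= k)
    Z <- cbind(z1, 1 - z1)
    mvn_logdens(y, rep(b0, n), Sig + tcrossprod(Z) / h0)
  }, numeric(1))
  p <- exp(ll - max(ll))
  stats::setNames(p / sum(p), sup)
}

# exhaustive-scan HDI: try every window of ceiling(mass*n) sorted draws
hdi_scan <- function(draws, mass = 0.95) {
  x <- sort(draws)
  n <- length(x)
  k <- ceiling(mass * n)
  if (k >= n) return(c(x[1], x[n]))
  best <- c(x[1], x[k])
  for (i in seq_len(n - k + 1)) {
    if (x[i + k - 1] - x[i] < best[2] - best[1])
      best <- c(x[i], x[i + k - 1])
  }
  best
}

# permutation p-value for |cor(y, v)| under exchangeability
perm_pvalue <- function(y, v, n_perm = 4000) {
  r_obs <- abs(cor(y, v))
  hits <- 0L
  for (b in seq_len(n_perm))
    hits <- hits + (abs(cor(sample(y), v)) >= r_obs)
  (hits + 1) / (n_perm + 1)
}

# total variation distance between a draw vector and an exact pmf
tv_distance <- function(draws, pmf) {
  emp <- table(factor(draws, levels = names(pmf))) / length(draws)
  0.5 * sum(abs(as.numeric(emp) - as.numeric(pmf)))
}
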