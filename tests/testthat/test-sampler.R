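test_that("the sampler is bit-reproducible under a fixed seed", {
  s <- simulate_sced(sim_preset("clear", seed = 4))
  st <- mcmc_settings(n_chains = 2, n_adapt = 100, n_samples = 300,
                      seed = 99)
  f1 <- suppressWarnings(bucp_fit(s, settings = st))
  f2 <- suppressWarnings(bucp_fit(s, settings = st))
  expect_identical(f1$draws, f2$draws)
  f3 <- suppressWarnings(
    bucp_fit(s, settings = mcmc_settings(n_chains = 2, n_adapt = 100,
                                         n_samples = 300, seed = 100)))
  expect_false(identical(f1$draws$beta1, f3$draws$beta1))
})

test_that("with rho, sigma and tau fixed, the intercept posterior matches
           the conjugate closed form", {
  set.seed(31)
  n <- 20L
  y <- c(rnorm(10, 1), rnorm(10, 4))
  s <- sced_series(y, design_cp = 11)
  h0 <- 0.25; b0 <- 0.5; sig <- 1
  pr <- bucp_priors(hierarchical = FALSE, beta_mean = b0,
                    beta_precision = h0)
  fit <- bucp_fit(s, priors = pr,
                  settings = mcmc_settings(n_chains = 2, n_adapt = 200,
                                           n_samples = 4000, seed = 31,
                                           fix_rho = 0, fix_sigma_eps = sig,
                                           fix_tau = 10L))
  # plain normal-normal update on each phase mean
  post_mean1 <- (sum(y[1:10]) / sig^2 + h0 * b0) / (10 / sig^2 + h0)
  post_sd1 <- 1 / sqrt(10 / sig^2 + h0)
  mcse <- post_sd1 / sqrt(nrow(fit$draws) / 5)  # conservative ESS
  expect_equal(mean(fit$draws$beta1), post_mean1, tolerance = 4 * mcse)
  expect_equal(sd(fit$draws$beta1), post_sd1, tolerance = 0.1 * post_sd1)
  post_mean2 <- (sum(y[11:20]) / sig^2 + h0 * b0) / (10 / sig^2 + h0)
  expect_equal(mean(fit$draws$beta2), post_mean2, tolerance = 4 * mcse)
})

test_that("the MCMC change-point marginal matches exact enumeration", {
  sc <- sim_scenario(n_a = 5, n_b = 5, beta1 = 0, beta2 = 2.5,
                     sigma_eps = 1, rho = 0.3, seed = 17)
  s <- simulate_sced(sc)
  pr <- bucp_priors(hierarchical = FALSE, beta_mean = 0,
                    beta_precision = 0.01)
  fit <- bucp_fit(s, priors = pr,
                  settings = mcmc_settings(n_chains = 2, n_adapt = 500,
                                           n_samples = 5000, seed = 17,
                                           fix_rho = 0.3,
                                           fix_sigma_eps = 1))
  oracle <- tau_marginal_integrated(s$values, rho = 0.3, sigma_eps = 1,
                                    b0 = 0, h0 = 0.01)
  expect_lt(tv_distance(fit$draws$tau, oracle), 0.05)
})

test_that("shifting the intervention phase shifts only the intervention
           intercept", {
  # with a clear change point the posterior puts all tau mass at the true
  # break, so adding c to phase B is an exact location shift of beta2
  s <- simulate_sced(sim_preset("clear", seed = 8))
  shift <- 3
  y2 <- s$values
  y2[s$design_cp:s$n] <- y2[s$design_cp:s$n] + shift
  s2 <- sced_series(y2, design_cp = s$design_cp)
  st <- mcmc_settings(n_chains = 2, n_adapt = 500, n_samples = 2500,
                      seed = 8)
  f1 <- bucp_fit(s, settings = st)
  f2 <- bucp_fit(s2, settings = st)
  expect_lt(abs(mean(f2$draws$beta2) - mean(f1$draws$beta2) - shift), 0.15)
  expect_lt(abs(mean(f2$draws$beta1) - mean(f1$draws$beta1)), 0.15)
  expect_lt(abs(mean(f2$draws$rho) - mean(f1$draws$rho)), 0.1)
  expect_lt(abs(mean(f2$draws$sigma_eps) - mean(f1$draws$sigma_eps)), 0.1)
})

test_that("PSRF is reported for the continuous parameters", {
  s <- simulate_sced(sim_preset("clear", seed = 12))
  fit <- bucp_fit(s, settings = fast_settings(12))
  expect_named(fit$psrf, c("beta1", "beta2", "rho", "sigma_eps"))
  expect_true(all(is.finite(fit$psrf)))
  expect_true(all(fit$psrf < 1.1))
  expect_length(fit$warnings, 0)
  # frozen-adaptation acceptance rate lands in the tuned band
  expect_gt(fit$rho_acceptance, 0.15)
  expect_lt(fit$rho_acceptance, 0.6)
})

test_that("simulation-based calibration ranks are uniform", {
  # draw parameters from the (non-hierarchical) prior, simulate data,
  # refit under the same prior, and rank the truth among thinned draws;
  # a correct sampler yields uniform ranks
  n_rep <- 40L
  n <- 12L
  L <- 100L
  ranks_b1 <- integer(n_rep)
  ranks_sig <- integer(n_rep)
  pr <- bucp_priors(hierarchical = FALSE, beta_mean = 0, beta_precision = 1,
                    error_precision_shape = 2, error_precision_rate = 2)
  set.seed(77)
  seeds <- sample.int(1e6, n_rep)
  for (i in seq_len(n_rep)) {
    set.seed(seeds[i])
    b1 <- rnorm(1); b2 <- rnorm(1)
    rho <- runif(1, -1, 1)
    sig <- 1 / sqrt(rgamma(1, 2, 2))
    tau <- sample(tau_support(n), 1)
    mu <- ifelse(seq_len(n) <= tau, b1, b2)
    y <- numeric(n)
    y[1] <- rnorm(1, mu[1], marginal_sd(sig, rho))
    for (t in 2:n) y[t] <- mu[t] + rho * (y[t - 1] - mu[t - 1]) +
        rnorm(1, 0, sig)
    s <- sced_series(y, design_cp = 7)
    fit <- suppressWarnings(
      bucp_fit(s, priors = pr,
               settings = mcmc_settings(n_chains = 1, n_adapt = 300,
                                        n_samples = L * 6, thin = 6,
                                        seed = seeds[i])))
    ranks_b1[i] <- sum(fit$draws$beta1 < b1)
    ranks_sig[i] <- sum(fit$draws$sigma_eps < sig)
  }
  # chi-squared uniformity check over 4 rank bins, liberal threshold
  for (r in list(ranks_b1, ranks_sig)) {
    bins <- table(cut(r, breaks = seq(0, L, length.out = 5),
                      include.lowest = TRUE))
    expect_gt(chisq.test(bins)$p.value, 1e-3)
  }
})

test_that("a strong step on a clear series is recovered", {
  s <- simulate_sced(sim_scenario(n_a = 15, n_b = 15, beta1 = 0, beta2 = 5,
                                  sigma_eps = 1, rho = 0.2, seed = 55))
  fit <- suppressWarnings(bucp_fit(s, settings = fast_settings(55)))
  expect_identical(tau_mode_of(fit), 15L)
  expect_lt(abs(mean(fit$draws$beta1) - 0), 1)
  expect_lt(abs(mean(fit$draws$beta2) - 5), 1)
})
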