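# shared fixture builders for the test suite

fast_settings <- function(seed, ...) {
  mcmc_settings(n_chains = 2L, n_adapt = 300L, n_samples = 1000L,
                seed = seed, ...)
}

# a minimal fake posterior object for inference-layer tests that do not need
# a real MCMC run
fake_fit <- function(draws, series) {
  structure(list(draws = draws, series = series,
                 settings = mcmc_settings(seed = 1L),
                 standardizer = "innovation_sd"),
            class = "bucp_fit")
}

tau_mode_of <- function(fit) {
  tb <- table(fit$draws$tau)
  as.integer(names(tb)[which.max(tb)])
}

flat_series <- function(n = 12L, design_cp = NULL, seed = 1L) {
  set.seed(seed)
  if (is.null(design_cp)) design_cp <- n %/% 2L + 1L
  sced_series(rnorm(n), design_cp = design_cp, label = "flat")
}
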