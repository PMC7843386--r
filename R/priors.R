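#' Prior specification for the BUCP model
#'
#' The default priors are deliberately weak. Each phase intercept is drawn
#' from a normal distribution whose mean is itself normal with mean 0 and
#' precision 0.0001 (standard deviation 100) and whose precision follows a
#' Gamma(shape 1, rate 1); the lag-1 autocorrelation is uniform on (-1, 1);
#' the change point is uniform over the admissible indices `3 .. n-3`, which
#' keeps at least three observations in each regime; and the innovation
#' precision 1/sigma_eps^2 follows a Gamma(shape, rate) with default (1, 1).
#' The innovation-scale prior is a package choice — nothing in the level
#' hierarchy pins it down — and is fully configurable here.
#'
#' With `hierarchical = FALSE` the intercept hyperpriors are dropped and each
#' intercept gets a fixed Normal(`beta_mean`, 1/`beta_precision`) prior. That
#' variant makes the change-point posterior available in closed form up to
#' enumeration (the intercepts integrate out conjugately), which is how the
#' sampler is validated.
#'
#' @param beta_hypermean_mean,beta_hypermean_precision normal hyperprior on
#'   the intercepts' common mean (precision 0.0001 corresponds to SD 100, see
#'   [precision_to_sd()]).
#' @param beta_precision_shape,beta_precision_rate gamma hyperprior on the
#'   intercepts' common precision.
#' @param rho_low,rho_high support of the uniform prior on the lag-1
#'   autocorrelation.
#' @param error_precision_shape,error_precision_rate gamma prior on the
#'   innovation precision 1/sigma_eps^2.
#' @param hierarchical logical; `FALSE` replaces the intercept hierarchy by a
#'   fixed normal prior.
#' @param beta_mean,beta_precision fixed intercept prior used when
#'   `hierarchical = FALSE`.
#' @return An object of class `bucp_priors`.
#' @export
bucp_priors <- function(beta_hypermean_mean = 0,
                        beta_hypermean_precision = 1e-4,
                        beta_precision_shape = 1,
                        beta_precision_rate = 1,
                        rho_low = -1, rho_high = 1,
                        error_precision_shape = 1,
                        error_precision_rate = 1,
                        hierarchical = TRUE,
                        beta_mean = 0, beta_precision = 1e-4) {
  stopifnot(beta_hypermean_precision > 0, beta_precision_shape > 0,
            beta_precision_rate > 0, error_precision_shape > 0,
            error_precision_rate > 0, beta_precision > 0,
            rho_low >= -1, rho_high <= 1, rho_low < rho_high)
  structure(list(
    beta_hypermean_mean = beta_hypermean_mean,
    beta_hypermean_precision = beta_hypermean_precision,
    beta_precision_shape = beta_precision_shape,
    beta_precision_rate = beta_precision_rate,
    rho_low = rho_low, rho_high = rho_high,
    error_precision_shape = error_precision_shape,
    error_precision_rate = error_precision_rate,
    hierarchical = isTRUE(hierarchical),
    beta_mean = beta_mean, beta_precision = beta_precision),
    class = "bucp_priors")
}

#' Convert a normal precision to a standard deviation (and back)
#'
#' Helpers used by the configuration layer: a precision of 0.0001 corresponds
#' to a standard deviation of 100.
#'
#' @param precision positive precision (1/variance).
#' @param sd positive standard deviation.
#' @return the corresponding standard deviation or precision.
#' @export
precision_to_sd <- function(precision) {
  stopifnot(is.numeric(precision), all(precision > 0))
  1 / sqrt(precision)
}

#' @rdname precision_to_sd
#' @export
sd_to_precision <- function(sd) {
  stopifnot(is.numeric(sd), all(sd > 0))
  1 / sd^2
}

#' Admissible change-point values for a series of length n
#'
#' The change point tau indexes the last observation governed by the baseline
#' level. Requiring at least three observations per regime gives the support
#' `{3, 4, ..., n-3}`, over which the prior places equal mass.
#'
#' @param n series length (>= 6).
#' @return integer vector of admissible tau values.
#' @export
tau_support <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 6L)
    stop("change-point support requires n >= 6, got ", n, call. = FALSE)
  3:(n - 3L)
}

#' MCMC settings for the BUCP sampler
#'
#' @param n_chains number of independent chains (default 4).
#' @param n_adapt burn-in iterations per chain (default 2000); the
#'   random-walk proposal scale for rho is tuned here and then frozen.
#' @param n_samples retained iterations per chain (default 10000).
#' @param thin keep every `thin`-th retained draw.
#' @param seed master seed; per-chain seeds are derived from it
#'   deterministically, so a fit is bit-reproducible.
#' @param rho_proposal_sd initial random-walk SD for the rho update.
#' @param psrf_threshold convergence warning threshold for the potential
#'   scale reduction factor (default 1.1).
#' @param fix_rho,fix_sigma_eps,fix_tau optional values at which to hold a
#'   parameter fixed instead of sampling it (used for validation against
#'   enumeration oracles and conjugate closed forms).
#' @return An object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_chains = 4L, n_adapt = 2000L, n_samples = 10000L,
                          thin = 1L, seed = 1L, rho_proposal_sd = 0.1,
                          psrf_threshold = 1.1,
                          fix_rho = NULL, fix_sigma_eps = NULL,
                          fix_tau = NULL) {
  stopifnot(n_chains >= 1L, n_adapt >= 0L, n_samples >= 1L, thin >= 1L,
            rho_proposal_sd > 0)
  if (!is.null(fix_rho)) stopifnot(abs(fix_rho) < 1)
  if (!is.null(fix_sigma_eps)) stopifnot(fix_sigma_eps > 0)
  structure(list(
    n_chains = as.integer(n_chains), n_adapt = as.integer(n_adapt),
    n_samples = as.integer(n_samples), thin = as.integer(thin),
    seed = as.integer(seed), rho_proposal_sd = rho_proposal_sd,
    psrf_threshold = psrf_threshold,
    fix_rho = fix_rho, fix_sigma_eps = fix_sigma_eps,
    fix_tau = if (is.null(fix_tau)) NULL else as.integer(fix_tau)),
    class = "mcmc_settings")
}
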