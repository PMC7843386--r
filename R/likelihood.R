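#' BUCP parameter vector
#'
#' Bundles one point in the BUCP parameter space: the baseline and
#' intervention intercepts (outcome units), the lag-1 autocorrelation of the
#' errors, the innovation standard deviation, and the change point `tau` —
#' the index of the last observation generated at the baseline level.
#'
#' @param beta1,beta2 phase intercepts.
#' @param rho lag-1 autocorrelation, in (-1, 1).
#' @param sigma_eps innovation SD, > 0. The marginal (stationary) error SD is
#'   `sigma_eps / sqrt(1 - rho^2)`.
#' @param tau integer change point; admissibility against a series length is
#'   checked where a series is present.
#' @return An object of class `bucp_params`.
#' @export
bucp_params <- function(beta1, beta2, rho, sigma_eps, tau) {
  if (abs(rho) >= 1) stop("|rho| must be < 1", call. = FALSE)
  if (sigma_eps <= 0) stop("sigma_eps must be > 0", call. = FALSE)
  structure(list(beta1 = beta1, beta2 = beta2, rho = rho,
                 sigma_eps = sigma_eps, tau = as.integer(tau)),
            class = "bucp_params")
}

#' Marginal error SD of a stationary AR(1) process
#'
#' @param sigma_eps innovation SD.
#' @param rho lag-1 autocorrelation, |rho| < 1.
#' @return `sigma_eps / sqrt(1 - rho^2)`.
#' @export
marginal_sd <- function(sigma_eps, rho) {
  stopifnot(all(abs(rho) < 1), all(sigma_eps > 0))
  sigma_eps / sqrt(1 - rho^2)
}

# log-likelihood at every candidate change point in `support`, vectorized.
#
# The model: mu_t = beta1 for t <= tau, beta2 after; errors follow a
# continuous AR(1) that does not reset at tau. Conditioning on y_{t-1},
# y_t ~ N(mu_t + rho * (y_{t-1} - mu_{t-1}), sigma_eps^2) for t >= 2.
# The first observation uses the stationary marginal variance
# sigma_e^2 = sigma_eps^2 / (1 - rho^2) by default; init_variance =
# "literal" uses sigma_eps^2 instead.
#
# Writing r_t = y_t - rho*y_{t-1}, d = beta2 - beta1 and
# a_t = r_t - beta1*(1-rho), the conditional residual at candidate k is
# a_t - d*c_t(k) with c_t(k) = 0 for t <= k, 1 at t = k+1, (1-rho) beyond,
# so the sum of squares over t >= 2 collapses to cumulative sums and the
# whole support costs O(n).
loglik_all_tau <- function(y, beta1, beta2, rho, sigma_eps,
                           support, init_variance = "stationary") {
  n <- length(y)
  d <- beta2 - beta1
  sd1 <- if (init_variance == "literal") sigma_eps
         else marginal_sd(sigma_eps, rho)
  term1 <- stats::dnorm(y[1L], mean = beta1, sd = sd1, log = TRUE)
  r <- y[-1L] - rho * y[-n]            # r[i] is r_{i+1}, i = 1..n-1
  a <- r - beta1 * (1 - rho)
  cs <- cumsum(a)
  S <- cs[n - 1L]
  k <- support                          # 3 <= k <= n-3, so k+1 <= n-2
  sac <- a[k] + (1 - rho) * (S - cs[k]) # sum_t a_t c_t(k)
  scc <- 1 + (1 - rho)^2 * (n - k - 1L) # sum_t c_t(k)^2
  sse <- sum(a^2) - 2 * d * sac + d^2 * scc
  term1 - (n - 1L) * log(sigma_eps * sqrt(2 * pi)) - sse / (2 * sigma_eps^2)
}

#' Exact log-likelihood of the BUCP model
#'
#' Evaluates the AR(1) interrupted-time-series log density: the first
#' observation is normal with the stationary marginal SD
#' `sigma_eps / sqrt(1 - rho^2)` and each later observation is normal around
#' `mu_t + rho * (y_{t-1} - mu_{t-1})` with SD `sigma_eps`, where the level
#' `mu_t` equals `beta1` up to and including `tau` and `beta2` afterwards.
#' The error recursion runs uninterrupted across the change point — only the
#' level shifts.
#'
#' @param series an [sced_series()].
#' @param params a [bucp_params()]; `tau` must lie in [tau_support()] of the
#'   series length.
#' @param init_variance `"stationary"` (default) uses the marginal AR(1)
#'   variance for the first observation; `"literal"` uses the innovation
#'   variance.
#' @return the log-likelihood, a single number.
#' @export
bucp_loglik <- function(series, params,
                        init_variance = c("stationary", "literal")) {
  stopifnot(inherits(series, "sced_series"), inherits(params, "bucp_params"))
  init_variance <- match.arg(init_variance)
  sup <- tau_support(series$n)
  if (!(params$tau %in% sup))
    stop("tau = ", params$tau, " outside the admissible support ",
         min(sup), "..", max(sup), call. = FALSE)
  as.numeric(loglik_all_tau(series$values, params$beta1, params$beta2,
                            params$rho, params$sigma_eps,
                            support = params$tau,
                            init_variance = init_variance))
}

#' Exact full conditional of the change point
#'
#' Computes `p(tau = k | y, beta1, beta2, rho, sigma_eps)` for every
#' admissible `k` by evaluating the likelihood at each candidate and
#' normalizing under the (by default uniform) discrete prior, with a
#' log-sum-exp guard. This is the categorical distribution the Gibbs sampler
#' draws `tau` from.
#'
#' @param series an [sced_series()].
#' @param beta1,beta2,rho,sigma_eps conditioning values.
#' @param prior_weights optional non-negative weights over the support
#'   (default uniform).
#' @param init_variance see [bucp_loglik()].
#' @return named numeric vector of probabilities over [tau_support()];
#'   sums to 1.
#' @export
tau_full_conditional <- function(series, beta1, beta2, rho, sigma_eps,
                                 prior_weights = NULL,
                                 init_variance = "stationary") {
  stopifnot(inherits(series, "sced_series"))
  if (abs(rho) >= 1 || sigma_eps <= 0)
    stop("need |rho| < 1 and sigma_eps > 0", call. = FALSE)
  sup <- tau_support(series$n)
  if (is.null(prior_weights)) prior_weights <- rep(1, length(sup))
  stopifnot(length(prior_weights) == length(sup), all(prior_weights >= 0),
            any(prior_weights > 0))
  ll <- loglik_all_tau(series$values, beta1, beta2, rho, sigma_eps,
                       support = sup, init_variance = init_variance)
  lw <- ll + log(prior_weights)
  lw <- lw - max(lw)
  p <- exp(lw)
  p <- p / sum(p)
  names(p) <- sup
  p
}
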