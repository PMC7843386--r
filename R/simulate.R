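#' Define a synthetic two-phase SCED scenario
#'
#' A scenario fixes the generative truth for one synthetic series: phase
#' lengths, the two levels, the AR(1) error structure, and an optional
#' latency — the number of post-intervention time points still generated at
#' the baseline level, so the true change point is `n_a + latency` while the
#' design change-point stays at `n_a + 1`.
#'
#' @param n_a,n_b phase lengths (each >= 3).
#' @param beta1,beta2 true baseline and intervention levels (outcome units).
#' @param sigma_eps innovation SD (> 0).
#' @param rho true lag-1 autocorrelation, |rho| < 1.
#' @param latency integer >= 0; must leave at least 3 points at the new
#'   level (`latency <= n_b - 3`).
#' @param seed seed for [simulate_sced()].
#' @param label series label.
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(n_a, n_b, beta1, beta2, sigma_eps, rho,
                         latency = 0L, seed = 1L, label = "synthetic") {
  n_a <- as.integer(n_a); n_b <- as.integer(n_b)
  latency <- as.integer(latency)
  if (n_a < 3L || n_b < 3L)
    stop("both phases need at least 3 points", call. = FALSE)
  if (latency < 0L || latency > n_b - 3L)
    stop("latency must be in [0, n_b - 3]", call. = FALSE)
  if (abs(rho) >= 1) stop("|rho| must be < 1", call. = FALSE)
  if (sigma_eps <= 0) stop("sigma_eps must be > 0", call. = FALSE)
  structure(list(n_a = n_a, n_b = n_b, beta1 = beta1, beta2 = beta2,
                 sigma_eps = sigma_eps, rho = rho, latency = latency,
                 seed = as.integer(seed), label = label),
            class = "sim_scenario")
}

#' Scenario presets for the three qualitative immediacy regimes
#'
#' Three ready-made scenarios span the patterns seen in applied two-phase
#' series:
#'
#' * `clear` — immediate, unmistakable effect: 15 + 15 points, a level step
#'   of 5 innovation SDs at the design change-point, `rho = 0.2`.
#' * `delayed` — a short series (8 + 9 points) where a large step (10
#'   innovation SDs) arrives 3 points after the intervention starts, so the
#'   true change point is 11 while the design change-point is 9.
#' * `unclear` — a weak, late-arriving effect in noisier data: 7 + 16
#'   points, a step of 1.5 innovation SDs, `rho = 0.2`, with the latency
#'   drawn uniformly from the middle of the intervention phase (4-8 points)
#'   so the onset is genuinely ambiguous.
#'
#' @param name preset name.
#' @param seed seed; for `unclear` it also drives the latency draw.
#' @return A [sim_scenario()].
#' @export
sim_preset <- function(name = c("clear", "delayed", "unclear"), seed = 1L) {
  name <- match.arg(name)
  switch(name,
    clear = sim_scenario(n_a = 15L, n_b = 15L, beta1 = 0, beta2 = 5,
                         sigma_eps = 1, rho = 0.2, latency = 0L,
                         seed = seed, label = "preset-clear"),
    delayed = sim_scenario(n_a = 8L, n_b = 9L, beta1 = 0, beta2 = 10,
                           sigma_eps = 1, rho = 0.2, latency = 3L,
                           seed = seed, label = "preset-delayed"),
    unclear = {
      set.seed((seed + 9973L) %% 2147483647L)
      lat <- sample(4:8, 1L)
      sim_scenario(n_a = 7L, n_b = 16L, beta1 = 0, beta2 = 3,
                   sigma_eps = 2, rho = 0.2, latency = lat,
                   seed = seed, label = "preset-unclear")
    })
}

#' Simulate a two-phase SCED series with AR(1) errors
#'
#' Generates exactly the process the BUCP model assumes: the first
#' observation is normal around the baseline level with the stationary
#' marginal SD `sigma_eps / sqrt(1 - rho^2)`; each later observation is
#' `mu_t + rho * (y_{t-1} - mu_{t-1}) + eps_t` with independent
#' `eps_t ~ N(0, sigma_eps^2)`. The level `mu_t` is `beta1` through the true
#' change point `n_a + latency` and `beta2` after; the error process runs
#' continuously across the change — only the level shifts.
#'
#' @param scenario a [sim_scenario()].
#' @return An [sced_series()] with `design_cp = n_a + 1` and an attribute
#'   `truth`: a list with the true change point `tau`, the scenario, and the
#'   true effect size `(beta2 - beta1) / sigma_eps`. Bit-reproducible given
#'   the scenario seed.
#' @export
simulate_sced <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  sc <- scenario
  n <- sc$n_a + sc$n_b
  tau <- sc$n_a + sc$latency
  mu <- ifelse(seq_len(n) <= tau, sc$beta1, sc$beta2)
  set.seed(sc$seed)
  y <- numeric(n)
  y[1L] <- stats::rnorm(1L, mu[1L], marginal_sd(sc$sigma_eps, sc$rho))
  eps <- stats::rnorm(n - 1L, 0, sc$sigma_eps)
  for (t in 2:n)
    y[t] <- mu[t] + sc$rho * (y[t - 1L] - mu[t - 1L]) + eps[t - 1L]
  out <- sced_series(y, design_cp = sc$n_a + 1L, label = sc$label)
  attr(out, "truth") <- list(tau = tau, scenario = sc,
                             effect_size = (sc$beta2 - sc$beta1) /
                               sc$sigma_eps)
  out
}

#' Read the truth record of a simulated series
#'
#' @param series a series produced by [simulate_sced()].
#' @return the truth list, or `NULL` for observed data.
#' @export
sim_truth <- function(series) attr(series, "truth")

#' Write a simulated series plus its truth sidecar
#'
#' Writes the series as CSV via [write_sced_csv()] and the truth record
#' (true change point, scenario parameters, true effect size) as a JSON
#' sidecar `<path>.truth.json`, so test harnesses never have to parse truth
#' out of a data file.
#'
#' @param series a series from [simulate_sced()].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_simulated <- function(series, path) {
  truth <- sim_truth(series)
  if (is.null(truth))
    stop("series carries no truth record; was it simulated?", call. = FALSE)
  write_sced_csv(series, path)
  sc <- truth$scenario
  jl <- list(tau = truth$tau, effect_size = truth$effect_size,
             scenario = sc[setdiff(names(sc), "label")],
             label = sc$label)
  jsonlite::write_json(jl, paste0(path, ".truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
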