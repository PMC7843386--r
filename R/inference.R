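#' Highest density interval of a sample
#'
#' Returns the narrowest contiguous interval containing `ceiling(mass * n)`
#' of the sorted draws — for a unimodal posterior, the interval of most
#' credible values. For symmetric samples it coincides with the equal-tailed
#' interval; for skewed ones it is shorter.
#'
#' @param draws numeric vector of at least 100 posterior draws.
#' @param mass probability mass to cover, in (0, 1); default 0.95.
#' @return numeric vector `c(lower, upper)`.
#' @export
hdi <- function(draws, mass = 0.95) {
  draws <- as.numeric(draws)
  if (length(draws) < 100L)
    stop("hdi() needs at least 100 draws, got ", length(draws),
         call. = FALSE)
  if (!is.numeric(mass) || length(mass) != 1L || mass <= 0 || mass >= 1)
    stop("'mass' must be a probability strictly between 0 and 1",
         call. = FALSE)
  x <- sort(draws)
  n <- length(x)
  k <- ceiling(mass * n)
  if (k >= n) return(c(x[1L], x[n]))
  widths <- x[(k):n] - x[seq_len(n - k + 1L)]
  i <- which.min(widths)
  c(x[i], x[i + k - 1L])
}

#' Per-draw standardized mean-difference effect size
#'
#' The effect size of the BUCP model is the standardized difference of the
#' two phase intercepts, computed draw by draw so it inherits a full
#' posterior distribution. The denominator is either the innovation SD
#' `sigma_eps` (default) or the marginal AR(1) error SD
#' `sigma_eps / sqrt(1 - rho^2)`; at `rho = 0` the two agree exactly. The
#' sign is preserved — a deterioration keeps its negative sign.
#'
#' @param fit a [bucp_fit()].
#' @param standardizer `"innovation_sd"` or `"marginal_sd"`.
#' @return An object of class `es_draws`: numeric vector of per-draw effect
#'   sizes with attribute `standardizer`.
#' @export
effect_size_draws <- function(fit,
                              standardizer = c("innovation_sd",
                                               "marginal_sd")) {
  stopifnot(inherits(fit, "bucp_fit"))
  standardizer <- match.arg(standardizer)
  d <- fit$draws
  s <- if (standardizer == "innovation_sd") d$sigma_eps
       else marginal_sd(d$sigma_eps, d$rho)
  es <- (d$beta2 - d$beta1) / s
  structure(es, standardizer = standardizer, class = "es_draws")
}

#' Classify immediacy of the intervention effect
#'
#' The change-point posterior carries the evidence on immediacy: the effect
#' is immediate when the posterior mode of `tau` (last baseline-level
#' observation) sits exactly at `design_cp - 1` — i.e. the level shifts at
#' the very first intervention observation — with a concentrated posterior;
#' it is delayed when a concentrated mode falls later. The concentration
#' requirement is operationalized as the posterior mass at the mode reaching
#' `mass_threshold` (default 0.5, which guarantees a unique majority mode);
#' anything less, a tie among modes, or a mode before the design
#' change-point is classified as unclear.
#'
#' @param fit a [bucp_fit()].
#' @param mass_threshold minimum posterior mass at the mode for a clear
#'   verdict.
#' @return An object of class `immediacy_verdict`: list with `tau_mode`,
#'   `tau_posterior_sd`, `mass_at_mode`, `category` (one of `"immediate"`,
#'   `"delayed"`, `"unclear"`), `multimodal` and the `design_cp` echoed.
#' @export
classify_immediacy <- function(fit, mass_threshold = 0.5) {
  stopifnot(inherits(fit, "bucp_fit"),
            mass_threshold > 0, mass_threshold <= 1)
  tm <- tau_mode(fit$draws$tau)
  design_cp <- fit$series$design_cp
  category <- if (tm$multimodal || tm$mass < mass_threshold) "unclear"
  else if (tm$mode == design_cp - 1L) "immediate"
  else if (tm$mode > design_cp - 1L) "delayed"
  else "unclear"
  structure(list(tau_mode = tm$mode,
                 tau_posterior_sd = stats::sd(fit$draws$tau),
                 mass_at_mode = tm$mass,
                 multimodal = tm$multimodal,
                 category = category,
                 design_cp = design_cp),
            class = "immediacy_verdict")
}

#' @export
print.immediacy_verdict <- function(x, ...) {
  cat("Immediacy: ", x$category, "\n", sep = "")
  cat("  change-point posterior mode ", x$tau_mode,
      " (mass ", format(x$mass_at_mode, digits = 3),
      ", posterior SD ", format(x$tau_posterior_sd, digits = 3), ")\n",
      sep = "")
  cat("  design change-point ", x$design_cp,
      " (immediate would put the mode at ", x$design_cp - 1L, ")\n",
      sep = "")
  if (x$multimodal) cat("  note: tied posterior modes\n")
  invisible(x)
}

#' ROPE-style decision on the effect size
#'
#' Compares the HDI of the posterior effect-size distribution against a
#' clinical-significance cut-off. The effect is accepted when the HDI lower
#' bound is at or above `threshold` (every credible value is clinically
#' meaningful); the null is accepted when the whole HDI lies inside the null
#' region (by default `(-threshold, threshold)`); otherwise the data leave
#' the question undecided. The default cut-off of 3 reflects that
#' standardized mean differences of 3 or more are common in single-case
#' designs, where the between-subject small/medium/large rules of thumb do
#' not apply; it is an illustrative default, not a universal standard.
#'
#' @param es an `es_draws` vector from [effect_size_draws()] (any numeric
#'   vector of draws works).
#' @param threshold clinical-significance cut-off (default 3).
#' @param mass HDI mass (default 0.95).
#' @param null_region length-2 numeric; the region of practical equivalence
#'   to zero. Defaults to `(-threshold, threshold)`.
#' @return An object of class `rope_decision`: list with `threshold`,
#'   `hdi` bounds, `fraction_above` (share of draws at or above the
#'   threshold) and `decision` (`"accept_effect"`, `"accept_null"` or
#'   `"undecided"`).
#' @export
rope_test <- function(es, threshold = 3, mass = 0.95, null_region = NULL) {
  es <- as.numeric(es)
  if (is.null(null_region)) null_region <- c(-threshold, threshold)
  stopifnot(length(null_region) == 2L, null_region[1L] < null_region[2L])
  iv <- hdi(es, mass = mass)
  decision <- if (iv[1L] >= threshold) "accept_effect"
  else if (iv[1L] > null_region[1L] && iv[2L] < null_region[2L] &&
           iv[2L] < threshold) "accept_null"
  else "undecided"
  structure(list(threshold = threshold, mass = mass, hdi = iv,
                 fraction_above = mean(es >= threshold),
                 null_region = null_region, decision = decision),
            class = "rope_decision")
}

#' @export
print.rope_decision <- function(x, ...) {
  cat("ROPE decision: ", x$decision, "\n", sep = "")
  cat("  ", format(100 * x$mass), "% HDI of the effect size: [",
      format(x$hdi[1L], digits = 3), ", ", format(x$hdi[2L], digits = 3),
      "]; cut-off ", x$threshold, "\n", sep = "")
  cat("  fraction of draws >= cut-off: ",
      format(x$fraction_above, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Highest-mass set of the discrete change-point posterior
#'
#' For the discrete `tau` the analogue of an HDI is the smallest set of
#' support points whose total posterior mass reaches `mass`; it need not be
#' contiguous.
#'
#' @param fit a [bucp_fit()].
#' @param mass target posterior mass.
#' @return integer vector of change-point values, sorted.
#' @export
tau_hpd_set <- function(fit, mass = 0.95) {
  stopifnot(inherits(fit, "bucp_fit"))
  tb <- sort(table(fit$draws$tau), decreasing = TRUE)
  p <- as.numeric(tb) / length(fit$draws$tau)
  k <- which(cumsum(p) >= mass)[1L]
  sort(as.integer(names(tb)[seq_len(k)]))
}

#' Summarize a BUCP fit as a result bundle
#'
#' Flattens the posterior into the row schema of [result_bundle()]:
#' posterior means and 95% HDIs for `beta1`, `beta2`, `rho`, `sigma_eps` and
#' the effect size `es`, and the posterior mode with its highest-mass set
#' bounds for `tau`.
#'
#' @param fit a [bucp_fit()].
#' @param mass HDI mass.
#' @return A [result_bundle()] with method `"bucp"`.
#' @export
bucp_bundle <- function(fit, mass = 0.95) {
  stopifnot(inherits(fit, "bucp_fit"))
  d <- fit$draws
  cont <- c("beta1", "beta2", "rho", "sigma_eps", "es")
  rows <- do.call(rbind, lapply(cont, function(p) {
    iv <- hdi(d[[p]], mass = mass)
    data.frame(parameter = p, estimate = mean(d[[p]]),
               lower = iv[1L], upper = iv[2L])
  }))
  tm <- tau_mode(d$tau)
  hpd <- tau_hpd_set(fit, mass)
  rows <- rbind(rows, data.frame(parameter = "tau", estimate = tm$mode,
                                 lower = min(hpd), upper = max(hpd)))
  result_bundle(fit$series$label, "bucp", rows,
                seed = fit$settings$seed,
                settings = list(n_chains = fit$settings$n_chains,
                                n_samples = fit$settings$n_samples,
                                n_adapt = fit$settings$n_adapt,
                                standardizer = fit$standardizer))
}
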