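test_that("hdi returns the narrowest window of sorted draws", {
  expect_equal(hdi(1:100, 0.95), c(1, 95))
  expect_equal(hdi(rep(2.5, 150)), c(2.5, 2.5))
  expect_error(hdi(1:99), "at least 100")
  expect_error(hdi(1:200, mass = 0), "probability")
  expect_error(hdi(1:200, mass = 1), "probability")

  # skewed and multimodal samples against the exhaustive scan oracle
  set.seed(13)
  for (rep in 1:8) {
    draws <- switch(1 + rep %% 3,
                    rgamma(500, shape = 2),
                    c(rnorm(300), rnorm(200, 6)),
                    rnorm(400))
    for (mass in c(0.5, 0.9, 0.95)) {
      got <- hdi(draws, mass)
      want <- hdi_scan(draws, mass)
      expect_equal(got, want)
      # no narrower valid window exists
      expect_lte(got[2] - got[1],
                 diff(quantile(draws, c((1 - mass) / 2,
                                        1 - (1 - mass) / 2))) + 1e-12)
    }
  }
})

test_that("hdi of a symmetric sample is close to the equal-tailed interval",
{
  set.seed(5)
  draws <- rnorm(50000)
  expect_equal(hdi(draws, 0.95),
               unname(quantile(draws, c(0.025, 0.975))),
               tolerance = 0.05)
})

test_that("effect size draws standardize the intercept difference", {
  s <- flat_series(12, design_cp = 6)
  d <- data.frame(chain = 1L, iter = 1:3,
                  beta1 = c(33.9, 1, 0), beta2 = c(61.2, 1, 3),
                  rho = c(0, 0, 0.6), sigma_eps = c(5, 1, 2),
                  tau = c(5L, 5L, 5L), es = NA_real_)
  fit <- fake_fit(d, s)
  es <- effect_size_draws(fit)
  # a level shift of 27.3 outcome units with innovation SD 5 is 5.46 SDs
  expect_equal(as.numeric(es), c(5.46, 0, 1.5))
  expect_identical(attr(es, "standardizer"), "innovation_sd")

  es_m <- effect_size_draws(fit, "marginal_sd")
  # with rho = 0 the two standardizers agree exactly
  expect_equal(es_m[1:2], es[1:2])
  # with rho = 0.6 the marginal SD is 2/0.8 = 2.5, so ES shrinks
  expect_equal(as.numeric(es_m[3]), 3 / 2.5)
  # sign is preserved, never folded
  d$beta2 <- d$beta1 - 1
  expect_true(all(effect_size_draws(fake_fit(d, s)) < 0))
})

test_that("immediacy classification follows the change-point posterior", {
  s <- flat_series(20, design_cp = 10)
  mk <- function(taus) {
    n <- length(taus)
    fake_fit(data.frame(chain = 1L, iter = seq_len(n), beta1 = 0, beta2 = 1,
                        rho = 0, sigma_eps = 1, tau = as.integer(taus),
                        es = 1), s)
  }
  # all mass at design_cp - 1: immediate
  v <- classify_immediacy(mk(rep(9L, 500)))
  expect_identical(v$category, "immediate")
  expect_identical(v$tau_mode, 9L)
  expect_equal(v$mass_at_mode, 1)
  expect_equal(v$tau_posterior_sd, 0)

  # concentrated three points after the intervention start: delayed
  v <- classify_immediacy(mk(rep(12L, 500)))
  expect_identical(v$category, "delayed")
  expect_identical(v$tau_mode, 12L)

  # near-uniform posterior: unclear
  v <- classify_immediacy(mk(rep(tau_support(20), each = 30)))
  expect_identical(v$category, "unclear")

  # dominant mode before the design change-point: unclear, not immediate
  v <- classify_immediacy(mk(c(rep(6L, 400), rep(9L, 100))))
  expect_identical(v$category, "unclear")

  # tied modes are flagged and classified unclear
  v <- classify_immediacy(mk(rep(c(9L, 12L), each = 250)))
  expect_true(v$multimodal)
  expect_identical(v$category, "unclear")
  expect_identical(v$tau_mode, 9L)  # smallest tied mode reported
})

test_that("rope decisions follow the HDI against the cut-off", {
  set.seed(3)
  # all credible values comfortably above 3: accept the effect
  r <- rope_test(runif(1000, 4.6, 6.4), threshold = 3)
  expect_identical(r$decision, "accept_effect")
  expect_equal(r$fraction_above, 1)

  # HDI straddles the cut-off: undecided
  r <- rope_test(runif(1000, 0.14, 5.37), threshold = 3)
  expect_identical(r$decision, "undecided")

  # whole HDI inside the null region: accept the null
  r <- rope_test(rnorm(1000, 0, 0.1), threshold = 3)
  expect_identical(r$decision, "accept_null")

  # boundary inclusive: draws exactly at the cut-off accept the effect
  r <- rope_test(rep(3, 500), threshold = 3)
  expect_identical(r$decision, "accept_effect")
})

test_that("adding a positive constant never downgrades the rope decision", {
  set.seed(7)
  base <- rnorm(800, 1, 0.8)
  rank_of <- c(accept_null = 1, undecided = 2, accept_effect = 3)
  last <- rank_of[[rope_test(base)$decision]]
  for (c0 in seq(0.5, 6, by = 0.5)) {
    now <- rank_of[[rope_test(base + c0)$decision]]
    expect_gte(now, last)
    last <- now
  }
})

test_that("the discrete change-point HPD set collects highest-mass values",
{
  s <- flat_series(20, design_cp = 10)
  taus <- c(rep(9L, 700), rep(12L, 250), rep(5L, 50))
  fit <- fake_fit(data.frame(chain = 1L, iter = seq_along(taus), beta1 = 0,
                             beta2 = 1, rho = 0, sigma_eps = 1, tau = taus,
                             es = 1), s)
  expect_identical(tau_hpd_set(fit, 0.95), c(9L, 12L))
  expect_identical(tau_hpd_set(fit, 0.99), c(5L, 9L, 12L))
  expect_identical(tau_hpd_set(fit, 0.5), 9L)
})
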