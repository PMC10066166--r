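test_that("derived quantities follow the product rules exactly", {
  expect_equal(indirect_effect(0, 5), 0)
  expect_equal(indirect_variance(0, -0.2), list(variance = 0, sd = 0))
  expect_equal(moderation_index(0, 0.5), 0)
  # probe at zero reduces to the unconditional product
  expect_equal(conditional_indirect(0.7, 0.3, -0.2, 0),
               indirect_effect(0.7, -0.2))
  expect_error(indirect_variance(-0.1, 1), ">= 0")
})

test_that("conditional indirect effects are affine in the probe", {
  a <- 0.83; a3 <- 0.163; b <- -0.2145
  m <- seq(-2, 2, by = 0.5)
  vals <- conditional_indirect(a, a3, b, m)
  # finite-difference slope equals the moderation index to machine precision
  slopes <- diff(vals) / diff(m)
  expect_equal(slopes, rep(moderation_index(a3, b), length(slopes)),
               tolerance = 1e-12)
  # index = conditional(m+1) - conditional(m) for any m
  expect_equal(conditional_indirect(a, a3, b, 1.7) -
                 conditional_indirect(a, a3, b, 0.7),
               moderation_index(a3, b), tolerance = 1e-12)
})

test_that("Monte-Carlo intervals degenerate, cover zero symmetrically, and match brute force", {
  # zero covariance: the interval collapses onto the point product
  ci0 <- monte_carlo_ci(c(a = 0.5, b = -0.4), diag(c(0, 0)),
                        "product", seed = 1)
  expect_equal(ci0$lower, ci0$upper)
  expect_equal(ci0$point, -0.2)

  # b centred at zero: the product distribution is symmetric about zero
  ci <- monte_carlo_ci(c(a = 1, b = 0), diag(c(0.01, 0.01)), "product",
                       n_draws = 20000, seed = 2)
  expect_lt(ci$lower, 0)
  expect_gt(ci$upper, 0)
  expect_false(ci$significant)

  # percentile bounds agree with an independent brute-force product sample
  est <- c(a = 0.9, b = -0.21)
  V <- diag(c(0.065^2, 0.007^2))
  ci_big <- monte_carlo_ci(est, V, "product", n_draws = 1e6, seed = 3)
  set.seed(987)
  brute <- rnorm(1e6, 0.9, 0.065) * rnorm(1e6, -0.21, 0.007)
  q <- quantile(brute, c(0.025, 0.975), names = FALSE)
  expect_equal(ci_big$lower, q[1], tolerance = 1e-3)
  expect_equal(ci_big$upper, q[2], tolerance = 1e-3)

  # seeded draws are reproducible
  c1 <- monte_carlo_ci(est, V, "product", seed = 42)
  c2 <- monte_carlo_ci(est, V, "product", seed = 42)
  expect_identical(c(c1$lower, c1$upper), c(c2$lower, c2$upper))

  expect_error(monte_carlo_ci(c(a = 1, b = 1),
                              matrix(c(1, 2, 2, 1), 2), "product"),
               "positive semidefinite")
  expect_warning(monte_carlo_ci(est, V, "product", n_draws = 500, seed = 1),
                 "1000")
})

test_that("the three-model sequence recovers idealized truth and orders likelihoods", {
  p <- generative_params(n_countries = 20, n_per_country = 250, seed = 8)
  d <- generate_synthetic(p)
  res <- suppressWarnings(
    run_sequence(d$data, config = mediation_config(n_draws = 2000)))

  # nesting: log-likelihoods never decrease along the sequence
  expect_true(all(diff(res$logliks) >= -1e-6))
  expect_true(all(res$converged))

  # estimated indirect effect lies near the generating truth
  te <- true_effects(p)
  expect_equal(res$mediators$disclosure$indirect, te$disclosure$indirect,
               tolerance = 0.12)
  expect_equal(res$mediators$victimization$indirect,
               te$victimization$indirect, tolerance = 0.12)

  # internal identities at full precision
  for (nm in names(res$mediators)) {
    m <- res$mediators[[nm]]
    expect_equal(m$indirect, m$a * m$b, tolerance = 1e-10)
    expect_equal(m$index, m$a3 * m$b, tolerance = 1e-10)
    expect_equal(unname(m$conditional["high"] - m$conditional["low"]),
                 m$index * unname(diff(res$probes)), tolerance = 1e-10)
    expect_equal(m$indirect_sd, sqrt(m$indirect_variance), tolerance = 1e-12)
  }

  # probes sit one respondent-weighted sd either side of the moderator mean
  w <- d$data$stigma
  expect_equal(unname(res$probes), c(mean(w) - sd(w), mean(w) + sd(w)))
})

test_that("probe rules are configurable and explicit probes are honoured", {
  p <- generative_params(n_countries = 10, n_per_country = 60, seed = 14)
  d <- generate_synthetic(p)
  res <- suppressWarnings(run_sequence(
    d$data, config = mediation_config(probe_rule = "explicit",
                                      probes = c(0, 2), n_draws = 1000)))
  expect_equal(unname(res$probes), c(0, 2))
  m <- res$mediators$disclosure
  # probe at zero: the conditional effect reduces to the model-3 a times b
  expect_equal(unname(m$conditional["low"]), m$a_model3 * m$b,
               tolerance = 1e-10)
  # country-level probing uses country means, not respondent weighting
  res_c <- suppressWarnings(run_sequence(
    d$data, config = mediation_config(probe_rule = "country",
                                      n_draws = 1000)))
  wj <- tapply(d$data$stigma, d$data$country, mean)
  expect_equal(unname(res_c$probes),
               c(mean(wj) - sd(wj), mean(wj) + sd(wj)))
})

test_that("incomplete tables are rejected before any fitting", {
  p <- generative_params(n_countries = 4, n_per_country = 30, seed = 6)
  d <- generate_synthetic(p)
  d$data$disclosure[5] <- NA
  expect_error(run_sequence(d$data), "complete-case")
})
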