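test_that("group-mean centering splits predictors into within and between parts", {
  tab <- data.frame(g = c("a", "a", "b", "b"), x = c(0, 2, 10, 10))
  d <- group_mean_center(tab, "x", "g")
  expect_equal(d$within, c(-1, 1, 0, 0))
  expect_equal(d$between, c(1, 1, 10, 10)) # oracle: per-cluster means
  # within component sums to zero inside every cluster
  sums <- tapply(d$within, tab$g, sum)
  expect_true(all(abs(sums) < 1e-9 * nrow(tab)))
  expect_error(group_mean_center(data.frame(g = 1, x = NA), "x", "g"),
               "missing")
})

test_that("without random effects the fit collapses to least squares", {
  set.seed(21)
  tab <- data.frame(g = rep(1:4, each = 10), x = rnorm(40), z = rnorm(40))
  tab$y <- 1 + 0.5 * tab$x - 0.3 * tab$z + rnorm(40)
  sp <- mixed_spec("y", within = "x", between = "z", cluster = "g")
  f <- fit_mixed(sp, tab)
  ols <- lm(y ~ x + z, tab)
  expect_equal(unname(f$beta), unname(coef(ols)), tolerance = 1e-8)
  expect_equal(f$loglik, as.numeric(logLik(ols)))
  expect_length(f$tau, 0)
})

test_that("balanced random-intercept variance components match the ANOVA ML closed form", {
  J <- 5; n <- 20
  tab <- balanced_ri_data(J = J, n = n)
  # textbook ML closed form for balanced one-way data:
  #   sigma2 = SSW / (N - J);  sigma2 + n*tau = SSB / J  with SSB about ybar
  ybar_j <- tapply(tab$y, tab$g, mean)
  ybar <- mean(tab$y)
  ssw <- sum((tab$y - ybar_j[tab$g])^2)
  ssb <- n * sum((ybar_j - ybar)^2)
  sigma2_ml <- ssw / (J * n - J)
  tau_ml <- max(0, (ssb / J - sigma2_ml) / n)

  sp <- mixed_spec("y", random_intercept = TRUE, cluster = "g")
  f <- fit_mixed(sp, tab)
  expect_equal(unname(f$beta["(Intercept)"]), ybar, tolerance = 1e-6)
  expect_equal(f$sigma2, sigma2_ml, tolerance = 1e-6)
  expect_equal(unname(f$tau["var_intercept"]), tau_ml, tolerance = 1e-6)
})

test_that("noise-free data are interpolated exactly", {
  set.seed(5)
  tab <- data.frame(g = rep(1:6, each = 8), x = rnorm(48), z = rnorm(48))
  tab$y <- 2 - 0.7 * tab$x + 1.1 * tab$z
  sp <- mixed_spec("y", within = "x", between = "z", cluster = "g")
  f <- suppressWarnings(fit_mixed(sp, tab)) # lm warns on a perfect fit
  expect_equal(unname(f$beta), c(2, -0.7, 1.1), tolerance = 1e-6)
})

test_that("estimates are invariant to row order and cluster relabeling", {
  p <- generative_params(n_countries = 8, n_per_country = 40, seed = 13)
  tab <- generate_synthetic(p)$data
  tab$cp_w <- tab$cp - ave(tab$cp, tab$country)
  sp <- mixed_spec("disclosure", within = "cp_w", between = "age_years",
                   random_intercept = TRUE, random_slopes = "cp_w",
                   cluster = "country")
  f1 <- fit_mixed(sp, tab)
  set.seed(31)
  shuffled <- tab[sample(nrow(tab)), ]
  f2 <- fit_mixed(sp, shuffled)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-6)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
  relabeled <- tab
  new_names <- paste0("X", 8:1) # reverse the label order, keep membership
  relabeled$country <- new_names[as.integer(factor(tab$country))]
  f3 <- fit_mixed(sp, relabeled)
  expect_equal(f1$beta, f3$beta, tolerance = 1e-6)
  expect_equal(unname(f1$tau), unname(f3$tau), tolerance = 1e-5)
})

test_that("rank-deficient designs and single clusters fail loudly", {
  tab <- data.frame(g = rep(1:3, each = 5), x = rnorm(15))
  tab$x2 <- 2 * tab$x
  tab$y <- rnorm(15)
  sp <- mixed_spec("y", within = c("x", "x2"), cluster = "g")
  expect_error(fit_mixed(sp, tab), "collinear")
  one <- data.frame(g = 1, x = rnorm(5), y = rnorm(5))
  expect_error(fit_mixed(mixed_spec("y", within = "x", cluster = "g"), one),
               "2 clusters")
})

test_that("likelihood-ratio tests use 2*delta-loglik against the chi-square tail", {
  mk <- function(ll, n = 100) {
    structure(list(loglik = ll, n_obs = n, converged = TRUE),
              class = "mixed_fit_joint")
  }
  # equal likelihoods: no evidence
  r0 <- lr_test(mk(-500), mk(-500), df = 4)
  expect_equal(r0$delta_chi2, 0)
  expect_equal(r0$p_value, 1)
  # a half-delta of 1436.15 doubles to 2872.3
  r1 <- lr_test(mk(-1000), mk(-2436.15), df = 4)
  expect_equal(r1$delta_chi2, 2872.3, tolerance = 1e-9)
  # chi-square quantile table: 9.49 on 4 df sits at p ~ 0.05
  r2 <- lr_test(mk(-500), mk(-504.745), df = 4)
  expect_equal(r2$p_value, 0.05, tolerance = 2e-3)
  # tiny reversals are clamped at zero, not negative
  expect_equal(lr_test(mk(-500.0000001), mk(-500), df = 1)$delta_chi2, 0)
  expect_error(lr_test(mk(-1, 100), mk(-2, 99), df = 1), "rows")
})

test_that("a nested model never beats the full model's likelihood", {
  p <- generative_params(n_countries = 10, n_per_country = 50, seed = 17)
  tab <- generate_synthetic(p)$data
  tab$cp_w <- tab$cp - ave(tab$cp, tab$country)
  full <- fit_mixed(mixed_spec("disclosure", within = "cp_w",
                               between = "age_years",
                               random_intercept = TRUE,
                               random_slopes = "cp_w", cluster = "country"),
                    tab)
  reduced <- fit_mixed(mixed_spec("disclosure", within = "cp_w",
                                  random_intercept = TRUE,
                                  cluster = "country"), tab)
  expect_gte(full$loglik, reduced$loglik - 1e-6)
})
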