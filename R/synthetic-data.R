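# Synthetic multi-country survey generator. Emulates the nested structure
# the mediation models assume -- respondents in unequal country clusters, a
# bounded participation score built from four Bernoulli items, two mediators
# whose slopes vary by country, a country-level moderator acting on both
# a-paths -- under known true parameters, for recovery and coverage testing.
# It deliberately does not emulate the real survey's recruitment mechanism
# or item-nonresponse patterns.

#' True parameters for the synthetic generator
#'
#' Defaults sit in the neighbourhood of the magnitudes the estimators are
#' meant to detect in this literature: a strong participation-to-disclosure
#' within path (~0.89), a modest participation-to-victimization path
#' (~0.16), mediator-to-depression paths of about -0.21 and 0.47, random
#' slope spread of about 0.23 / 0.06 across countries, and a standardized
#' country moderator.
#'
#' @param n_countries Number of level-2 clusters.
#' @param n_per_country Scalar or length-\code{n_countries} vector of
#'   cluster sizes (each at least 2).
#' @param moderator_mean,moderator_sd Distribution of the country-level
#'   moderator W.
#' @param a_disc,a_vict True within a-paths (participation to mediator).
#' @param a3_disc,a3_vict True cross-level interactions on the a-paths.
#' @param b_disc,b_vict True mediator-to-outcome within paths.
#' @param c_prime True direct participation-to-depression effect.
#' @param tau0_disc,tau0_vict Random-intercept sds of the mediator
#'   equations.
#' @param tau1_disc,tau1_vict Random-slope sds of the mediator equations.
#' @param tau0_y Outcome random-intercept sd.
#' @param sigma_disc,sigma_vict,sigma_y Residual sds (\code{sigma_vict}
#'   applies only in idealized mode, where victimization is a Gaussian
#'   latent).
#' @param covariate_effects Named vector \code{c(age, ethnic, income)} of
#'   fixed covariate coefficients applied in every equation (age per year).
#' @param mode \code{"idealized"} (all equations Gaussian, satisfying every
#'   estimator assumption) or \code{"survey"} (disclosure clipped to
#'   \[0, 3\], victimization Bernoulli of the clipped linear predictor,
#'   depression rounded and clipped to 0-5).
#' @param seed Integer seed; generation is bit-reproducible.
#' @return Object of class \code{generative_params}.
#' @export
generative_params <- function(n_countries = 28,
                              n_per_country = 300,
                              moderator_mean = 0, moderator_sd = 1,
                              a_disc = 0.89, a_vict = 0.16,
                              a3_disc = 0.16, a3_vict = 0.04,
                              b_disc = -0.21, b_vict = 0.47,
                              c_prime = 0.13,
                              tau0_disc = 0.30, tau0_vict = 0.10,
                              tau1_disc = 0.23, tau1_vict = 0.06,
                              tau0_y = 0.25,
                              sigma_disc = 0.85, sigma_vict = 0.40,
                              sigma_y = 1.10,
                              covariate_effects = c(age = -0.005,
                                                    ethnic = 0.10,
                                                    income = -0.05),
                              mode = c("idealized", "survey"),
                              seed = 1L) {
  mode <- match.arg(mode)
  sds <- c(moderator_sd, tau0_disc, tau0_vict, tau1_disc, tau1_vict,
           tau0_y, sigma_disc, sigma_vict, sigma_y)
  if (any(sds < 0)) stop("standard deviations must be >= 0", call. = FALSE)
  n_per_country <- rep_len(as.integer(n_per_country), n_countries)
  if (any(n_per_country < 2L)) {
    stop("each country needs at least 2 respondents", call. = FALSE)
  }
  structure(as.list(environment()), class = "generative_params")
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic multi-country survey dataset
#'
#' Draws the country moderator, country random effects and respondent-level
#' variables under the supplied true parameters and returns an analysis
#' table in the same schema the survey-coding module produces, together
#' with the parameters and per-country true slopes.
#'
#' Participation is the mean of four Bernoulli items with country-varying
#' propensity, so it lands on the five-point grid. The a-paths act on the
#' empirically within-country-centered participation score, matching the
#' estimand of group-mean-centered fitting. In survey mode linear
#' predictors used as Bernoulli probabilities are clipped to \[0, 1\] and
#' the clip rate is recorded (a warning is raised above 10%).
#'
#' @param params \code{\link{generative_params}} object.
#' @return Object of class \code{synthetic_dataset}: \code{data} (analysis
#'   table with columns \code{country}, \code{subgroup}, \code{cp},
#'   \code{disclosure}, \code{victimization}, \code{depression},
#'   \code{age_years}, \code{ethnic_minority}, \code{income_level},
#'   \code{stigma}, \code{gdp_ppp}, \code{democracy_index}, \code{hdi}),
#'   \code{params}, \code{country} (per-country moderator, random effects
#'   and true slopes), \code{clip_rate}.
#' @export
generate_synthetic <- function(params) {
  stopifnot(inherits(params, "generative_params"))
  with_seed(params$seed, {
    p <- params
    J <- p$n_countries
    n_j <- p$n_per_country
    N <- sum(n_j)
    country_id <- sprintf("C%02d", seq_len(J))

    W <- stats::rnorm(J, p$moderator_mean, p$moderator_sd)
    u0_disc <- stats::rnorm(J, 0, p$tau0_disc)
    u1_disc <- stats::rnorm(J, 0, p$tau1_disc)
    u0_vict <- stats::rnorm(J, 0, p$tau0_vict)
    u1_vict <- stats::rnorm(J, 0, p$tau1_vict)
    u0_y <- stats::rnorm(J, 0, p$tau0_y)
    gdp <- stats::rnorm(J)
    dem <- stats::rnorm(J)
    hdi <- stats::rnorm(J)
    cp_prop <- stats::plogis(stats::qlogis(0.30) + stats::rnorm(J, 0, 0.5))

    g <- rep(seq_len(J), n_j)
    age <- sample(18:69, N, replace = TRUE)
    ethnic <- stats::rbinom(N, 1, 0.08)
    income <- sample(1:6, N, replace = TRUE,
                     prob = c(0.05, 0.09, 0.23, 0.29, 0.23, 0.11))
    items <- matrix(stats::rbinom(4L * N, 1, rep(cp_prop[g], each = 4)),
                    ncol = 4, byrow = TRUE)
    cp <- rowMeans(items)
    cp_w <- cp - stats::ave(cp, g)

    cov_lp <- p$covariate_effects[["age"]] * age +
      p$covariate_effects[["ethnic"]] * ethnic +
      p$covariate_effects[["income"]] * income

    slope_disc <- p$a_disc + p$a3_disc * W + u1_disc
    slope_vict <- p$a_vict + p$a3_vict * W + u1_vict

    lp_disc <- 1.8 + slope_disc[g] * cp_w + cov_lp + u0_disc[g]
    lp_vict <- 0.25 + slope_vict[g] * cp_w + cov_lp * 0.2 + u0_vict[g]

    clip_rate <- 0
    if (p$mode == "idealized") {
      disclosure <- lp_disc + stats::rnorm(N, 0, p$sigma_disc)
      victimization <- lp_vict + stats::rnorm(N, 0, p$sigma_vict)
    } else {
      disclosure <- pmin(3, pmax(0, lp_disc + stats::rnorm(N, 0, p$sigma_disc)))
      clip_rate <- mean(lp_vict < 0 | lp_vict > 1)
      prob <- pmin(1, pmax(0, lp_vict))
      victimization <- stats::rbinom(N, 1, prob)
      if (clip_rate > 0.10) {
        warning(sprintf("victimization probability clipped for %.1f%% of rows",
                        100 * clip_rate), call. = FALSE)
      }
    }

    lp_y <- 2.0 + p$c_prime * cp_w + p$b_disc * disclosure +
      p$b_vict * victimization + cov_lp + u0_y[g]
    depression <- lp_y + stats::rnorm(N, 0, p$sigma_y)
    if (p$mode == "survey") depression <- pmin(5, pmax(0, round(depression)))

    data <- data.frame(
      country = country_id[g],
      subgroup = "synthetic",
      cp = cp,
      disclosure = disclosure,
      victimization = victimization,
      depression = depression,
      age_years = age,
      ethnic_minority = ethnic,
      income_level = income,
      stigma = W[g],
      gdp_ppp = gdp[g],
      democracy_index = dem[g],
      hdi = hdi[g],
      stringsAsFactors = FALSE
    )
    country <- data.frame(
      country = country_id, n = n_j, W = W,
      u0_disc = u0_disc, u1_disc = u1_disc,
      u0_vict = u0_vict, u1_vict = u1_vict, u0_y = u0_y,
      slope_disc = slope_disc, slope_vict = slope_vict,
      stringsAsFactors = FALSE
    )
    structure(list(data = data, params = p, country = country,
                   clip_rate = clip_rate),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("Synthetic survey dataset: %d respondents in %d countries (%s mode, seed %d)\n",
              nrow(x$data), x$params$n_countries, x$params$mode,
              x$params$seed))
  invisible(x)
}

#' True derived mediation quantities implied by generator parameters
#'
#' Computes, from the true parameter values, the quantities the estimation
#' pipeline is meant to recover: indirect effects (a*b), indices of
#' moderated mediation (a3*b), conditional indirect effects at the
#' moderator mean plus/minus one sd, and the variance of country-specific
#' indirect effects (tau1^2 * b^2).
#'
#' @param params \code{\link{generative_params}} object.
#' @return Nested list keyed by mediator (\code{disclosure},
#'   \code{victimization}).
#' @export
true_effects <- function(params) {
  stopifnot(inherits(params, "generative_params"))
  p <- params
  probes <- c(low = p$moderator_mean - p$moderator_sd,
              high = p$moderator_mean + p$moderator_sd)
  one <- function(a, a3, b, tau1) {
    list(indirect = a * b,
         index = a3 * b,
         conditional = stats::setNames((a + a3 * probes) * b, names(probes)),
         indirect_variance = tau1^2 * b^2,
         indirect_sd = abs(tau1 * b))
  }
  list(disclosure = one(p$a_disc, p$a3_disc, p$b_disc, p$tau1_disc),
       victimization = one(p$a_vict, p$a3_vict, p$b_vict, p$tau1_vict),
       probes = probes,
       c_prime = p$c_prime)
}
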