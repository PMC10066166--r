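# Derived mediation quantities and the three-model estimation sequence.
#
# The a-paths (participation -> mediator) carry random slopes; the b-paths
# and the direct effect are fixed, so indirect effects are plain products
# with no slope-covariance correction term. Mediator and outcome equations
# are separate fits, so Monte-Carlo draws treat their parameter blocks as
# independent.

#' Indirect effect
#'
#' Product-of-coefficients indirect effect a*b of the predictor on the
#' outcome through a mediator.
#'
#' @param a Predictor-to-mediator within path.
#' @param b Mediator-to-outcome within path.
#' @return a * b.
#' @export
indirect_effect <- function(a, b) a * b

#' Variance of country-specific indirect effects
#'
#' With a random slope on the a-path only, the country-specific indirect
#' effect is (a + u1_j) * b, so its variance across countries is
#' tau1^2 * b^2.
#'
#' @param tau1_sq Random-slope variance of the a-path.
#' @param b Fixed mediator-to-outcome path.
#' @return List with \code{variance} and \code{sd}.
#' @export
indirect_variance <- function(tau1_sq, b) {
  if (any(tau1_sq < 0)) stop("tau1_sq must be >= 0", call. = FALSE)
  v <- tau1_sq * b^2
  list(variance = v, sd = sqrt(v))
}

#' Index of moderated mediation
#'
#' The change in the indirect effect per unit of the level-2 moderator:
#' the cross-level interaction on the a-path times the b-path.
#'
#' @param a3 Cross-level interaction coefficient (predictor x moderator on
#'   the mediator).
#' @param b Mediator-to-outcome path.
#' @return a3 * b.
#' @export
moderation_index <- function(a3, b) a3 * b

#' Conditional indirect effect
#'
#' The indirect effect at moderator value m: (a + a3*m) * b.
#'
#' @param a,a3,b Path coefficients.
#' @param m Moderator probe value(s).
#' @return Numeric vector, one value per probe.
#' @export
conditional_indirect <- function(a, a3, b, m) (a + a3 * m) * b

mc_transforms <- list(
  product = function(d) d[, "a"] * d[, "b"],
  index = function(d) d[, "a3"] * d[, "b"],
  conditional = NULL # built per-probe below
)

#' Monte-Carlo confidence interval for a function of coefficients
#'
#' Draws parameter vectors from a multivariate normal centred at the
#' estimates with the supplied covariance (cross-equation blocks zero),
#' applies the transform to every draw, and returns empirical percentile
#' bounds. Percentile (not bias-corrected) intervals are produced.
#'
#' @param estimate Named numeric vector of coefficient estimates. The
#'   built-in transforms expect names \code{a, b} (product), \code{a3, b}
#'   (index) or \code{a, a3, b} (conditional).
#' @param vcov Covariance matrix in the same order as \code{estimate};
#'   must be positive semidefinite.
#' @param transform \code{"product"}, \code{"index"}, \code{"conditional"},
#'   or a function taking the draw matrix (columns named as
#'   \code{estimate}) and returning one value per draw.
#' @param m Probe value, required for the conditional transform.
#' @param n_draws Number of Monte-Carlo samples (default 10000; below 1000
#'   a warning is raised).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed for the draws.
#' @return Object of class \code{mc_ci}: \code{point}, \code{lower},
#'   \code{upper}, \code{level}, \code{n_draws}, \code{seed},
#'   \code{significant} (zero outside the interval).
#' @export
monte_carlo_ci <- function(estimate, vcov, transform = "product", m = NULL,
                           n_draws = 10000, level = 0.95, seed = 1L) {
  vcov <- as.matrix(vcov)
  if (length(estimate) != nrow(vcov) || nrow(vcov) != ncol(vcov)) {
    stop("estimate and vcov dimensions disagree", call. = FALSE)
  }
  ev <- eigen(vcov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop("vcov is not positive semidefinite", call. = FALSE)
  }
  if (n_draws < 1000) {
    warning("fewer than 1000 Monte-Carlo draws; interval will be noisy",
            call. = FALSE)
  }
  fn <- if (is.function(transform)) {
    transform
  } else {
    switch(match.arg(transform, c("product", "index", "conditional")),
           product = mc_transforms$product,
           index = mc_transforms$index,
           conditional = {
             if (is.null(m)) stop("conditional transform needs a probe m",
                                  call. = FALSE)
             function(d) (d[, "a"] + d[, "a3"] * m) * d[, "b"]
           })
  }
  draws <- with_seed(seed, MASS::mvrnorm(n_draws, mu = estimate,
                                         Sigma = vcov))
  colnames(draws) <- names(estimate)
  vals <- fn(draws)
  alpha <- (1 - level) / 2
  q <- stats::quantile(vals, c(alpha, 1 - alpha), names = FALSE)
  point_draw <- matrix(estimate, nrow = 1,
                       dimnames = list(NULL, names(estimate)))
  structure(list(point = unname(fn(point_draw)), lower = q[1], upper = q[2],
                 level = level, n_draws = n_draws, seed = seed,
                 significant = q[1] > 0 || q[2] < 0),
            class = "mc_ci")
}

#' @export
print.mc_ci <- function(x, digits = 4, ...) {
  cat(sprintf("%.*f  %g%% MCCI [%.*f, %.*f]%s  (%d draws, seed %d)\n",
              digits, x$point, 100 * x$level, digits, x$lower, digits,
              x$upper, if (x$significant) " *" else "", x$n_draws, x$seed))
  invisible(x)
}

#' Configuration for the three-model sequence
#'
#' @param covariates Level-1 covariate columns.
#' @param country_covariates Level-2 covariate columns (model 3).
#' @param predictor,mediators,outcome,cluster Column names.
#' @param probe_rule \code{"respondent"} (probes at the respondent-weighted
#'   moderator mean +/- sd, the default), \code{"country"} (country-level
#'   mean/sd), or \code{"explicit"} with \code{probes} supplied.
#' @param probes Length-2 numeric (low, high) when
#'   \code{probe_rule = "explicit"}.
#' @param n_draws,level Monte-Carlo CI settings.
#' @param seed Integer seed for all Monte-Carlo draws.
#' @param diagonal Diagonal random-effect covariance (default) or free.
#' @return List of class \code{mediation_config}.
#' @export
mediation_config <- function(covariates = c("age_years", "ethnic_minority",
                                            "income_level"),
                             country_covariates = c("gdp_ppp",
                                                    "democracy_index", "hdi"),
                             predictor = "cp",
                             mediators = c(disclosure = "disclosure",
                                           victimization = "victimization"),
                             outcome = "depression",
                             cluster = "country",
                             probe_rule = c("respondent", "country",
                                            "explicit"),
                             probes = NULL,
                             n_draws = 10000, level = 0.95, seed = 20240601L,
                             diagonal = TRUE) {
  probe_rule <- match.arg(probe_rule)
  if (probe_rule == "explicit" && (is.null(probes) || length(probes) != 2)) {
    stop("explicit probing needs probes = c(low, high)", call. = FALSE)
  }
  structure(as.list(environment()), class = "mediation_config")
}

probe_points <- function(table, stigma_col, config) {
  switch(config$probe_rule,
         respondent = {
           w <- table[[stigma_col]]
           c(low = mean(w) - stats::sd(w), high = mean(w) + stats::sd(w))
         },
         country = {
           w <- tapply(table[[stigma_col]], table[[config$cluster]], mean)
           c(low = mean(w) - stats::sd(w), high = mean(w) + stats::sd(w))
         },
         explicit = c(low = config$probes[1], high = config$probes[2]))
}

#' Run the three-model moderated-mediation sequence for one subgroup
#'
#' Model 1 fits the two mediator equations with fixed effects only and the
#' outcome equation with a country random intercept (kept in every model so
#' likelihood-ratio tests of country-level terms are valid), the level-1
#' predictor decomposed into within and between components, adjusted for
#' the level-1 covariates.
#' Model 2 adds a random intercept and a random slope on the within a-path
#' to each mediator equation (diagonal covariance by default, so model 2
#' adds 4 variance parameters). Model 3 adds the country-level moderator
#' with a cross-level interaction on both a-paths plus the country
#' covariates to the mediator equations, and the moderator with its
#' cross-level interaction to the outcome equation (12 new fixed effects).
#' Likelihood-ratio tests compare the joint (summed) equation likelihoods.
#'
#' Indirect effects use the model-1 a and b paths; variance components of
#' country-specific indirect effects use the model-2 random-slope variance
#' with the model-1 b; indices of moderated mediation and conditional
#' indirect effects use the model-3 a and a3 with the model-1 b (a single
#' b per subgroup). Monte-Carlo confidence intervals draw mediator- and
#' outcome-equation parameters as independent blocks, using each
#' equation's fitted covariance.
#'
#' @param table Complete-case analysis table (see
#'   \code{\link{build_analysis_table}} or \code{\link{generate_synthetic}}).
#' @param stigma_col Name of the moderator column (default
#'   \code{"stigma"}).
#' @param config \code{\link{mediation_config}}.
#' @return Object of class \code{mediation_result}.
#' @export
run_sequence <- function(table, stigma_col = "stigma",
                         config = mediation_config()) {
  stopifnot(inherits(config, "mediation_config"))
  vars <- c(config$predictor, unname(config$mediators), config$outcome,
            config$covariates, stigma_col, config$country_covariates,
            config$cluster)
  miss <- setdiff(vars, names(table))
  if (length(miss)) {
    stop("analysis table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(table[, vars])) {
    stop("analysis table must be complete-case on all model variables",
         call. = FALSE)
  }
  cl <- config$cluster
  x <- config$predictor
  meds <- config$mediators
  table <- add_decomposition(table, c(x, unname(meds)), cl)
  xw <- paste0(x, "_w")
  xb <- paste0(x, "_b")

  # --- equation specs ------------------------------------------------------
  med_spec <- function(m, model) {
    mixed_spec(
      outcome = m,
      within = xw,
      between = c(xb, config$covariates,
                  if (model >= 3) c(stigma_col, config$country_covariates)),
      interactions = if (model >= 3) list(c(xw, stigma_col)) else list(),
      random_intercept = model >= 2,
      random_slopes = if (model >= 2) xw else character(),
      cluster = cl, diagonal = config$diagonal
    )
  }
  out_spec <- function(model) {
    # the outcome equation keeps a country random intercept in every model
    # (so LR tests of country-level fixed effects are valid), but never a
    # random slope: b-paths and the direct effect are fixed
    mixed_spec(
      outcome = config$outcome,
      within = c(xw, paste0(unname(meds), "_w")),
      between = c(xb, paste0(unname(meds), "_b"), config$covariates,
                  if (model >= 3) stigma_col),
      interactions = if (model >= 3) list(c(xw, stigma_col)) else list(),
      random_intercept = TRUE,
      random_slopes = character(),
      cluster = cl, diagonal = config$diagonal
    )
  }

  fits <- list()
  for (model in 1:3) {
    fits[[model]] <- c(
      lapply(unname(meds), function(m) fit_mixed(med_spec(m, model), table)),
      list(fit_mixed(out_spec(model), table))
    )
    names(fits[[model]]) <- c(names(meds), "outcome")
  }
  joint <- lapply(fits, joint_fit)
  lr_2v1 <- lr_test(joint[[2]], joint[[1]], df = 4)
  lr_3v2 <- lr_test(joint[[3]], joint[[2]], df = 12)

  out1 <- fits[[1]]$outcome
  if ("victimization" %in% unname(meds)) {
    lp_check <- fits[[1]][[which(unname(meds) == "victimization")[1]]]
    pr <- stats::fitted(lp_check$engine)
    n_out <- sum(pr < 0 | pr > 1)
    if (n_out > 0) {
      warning(sprintf(
        "linear-probability mediator: %d fitted probabilities outside [0,1]",
        n_out), call. = FALSE)
    }
  }

  probes <- probe_points(table, stigma_col, config)
  int_term <- paste0(xw, ":", stigma_col)

  seed_i <- 0L
  next_seed <- function() {
    seed_i <<- seed_i + 1L
    config$seed + seed_i
  }

  per_mediator <- function(name) {
    m_col <- meds[[name]]
    f1 <- fits[[1]][[name]]
    f2 <- fits[[2]][[name]]
    f3 <- fits[[3]][[name]]
    a <- unname(f1$beta[xw])
    a_se2 <- f1$vcov[xw, xw]
    b_name <- paste0(m_col, "_w")
    b <- unname(out1$beta[b_name])
    b_se2 <- out1$vcov[b_name, b_name]
    tau1 <- unname(f2$tau[paste0("var_", xw)])
    a3 <- unname(f3$beta[int_term])
    a_m3 <- unname(f3$beta[xw])
    v_a3 <- f3$vcov[c(xw, int_term), c(xw, int_term)]

    block2 <- function(v11, v22) diag(c(v11, v22))
    iv <- indirect_variance(tau1, b)
    cond <- conditional_indirect(a_m3, a3, b, probes)

    cond_ci <- lapply(probes, function(mm) {
      est <- c(a = a_m3, a3 = a3, b = b)
      V <- rbind(cbind(v_a3, 0), 0)
      V[3, 3] <- b_se2
      dimnames(V) <- list(names(est), names(est))
      monte_carlo_ci(est, V, "conditional", m = mm,
                     n_draws = config$n_draws, level = config$level,
                     seed = next_seed())
    })

    list(
      a = a, a_se = sqrt(a_se2), b = b, b_se = sqrt(b_se2),
      a_model3 = a_m3,
      a3 = a3, a3_se = sqrt(v_a3[int_term, int_term]),
      tau1_sq = tau1,
      indirect = indirect_effect(a, b),
      indirect_ci = monte_carlo_ci(
        c(a = a, b = b), block2(a_se2, b_se2), "product",
        n_draws = config$n_draws, level = config$level, seed = next_seed()),
      indirect_variance = iv$variance,
      indirect_sd = iv$sd,
      index = moderation_index(a3, b),
      index_ci = monte_carlo_ci(
        c(a3 = a3, b = b), block2(v_a3[int_term, int_term], b_se2), "index",
        n_draws = config$n_draws, level = config$level, seed = next_seed()),
      conditional = cond,
      conditional_ci = cond_ci
    )
  }

  mediation <- lapply(stats::setNames(names(meds), names(meds)), per_mediator)

  res <- structure(list(
    subgroup = if ("subgroup" %in% names(table)) table$subgroup[1] else NA,
    n_obs = nrow(table),
    n_clusters = length(unique(table[[cl]])),
    mediators = mediation,
    c_prime = unname(out1$beta[xw]),
    c_prime_se = unname(out1$se[xw]),
    probes = probes,
    lr_2v1 = lr_2v1,
    lr_3v2 = lr_3v2,
    logliks = vapply(joint, function(j) j$loglik, numeric(1)),
    converged = vapply(joint, function(j) j$converged, logical(1)),
    fits = fits,
    config = config
  ), class = "mediation_result")
  res
}

#' @export
print.mediation_result <- function(x, digits = 4, ...) {
  cat(sprintf("Multilevel moderated mediation: %s (n = %d, %d countries)\n",
              x$subgroup, x$n_obs, x$n_clusters))
  cat(sprintf("Probes (moderator low/high): %.*f / %.*f; MC seed %d\n",
              digits, x$probes["low"], digits, x$probes["high"],
              x$config$seed))
  for (nm in names(x$mediators)) {
    m <- x$mediators[[nm]]
    cat(sprintf("\n-- mediator: %s --\n", nm))
    cat(sprintf("  a = %.*f (%.*f)   b = %.*f (%.*f)   a3 = %.*f (%.*f)\n",
                digits, m$a, digits, m$a_se, digits, m$b, digits, m$b_se,
                digits, m$a3, digits, m$a3_se))
    cat("  indirect  "); print(m$indirect_ci, digits = digits)
    cat(sprintf("  variance of country indirect effects: %.*f (sd %.*f)\n",
                digits, m$indirect_variance, digits, m$indirect_sd))
    cat("  index     "); print(m$index_ci, digits = digits)
    cat("  cond(low) "); print(m$conditional_ci$low, digits = digits)
    cat("  cond(high)"); print(m$conditional_ci$high, digits = digits)
  }
  cat(sprintf("\nDirect effect c' = %.*f (%.*f)\n", digits, x$c_prime,
              digits, x$c_prime_se))
  cat("Model fit: "); print(x$lr_2v1)
  cat("           "); print(x$lr_3v2)
  invisible(x)
}
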