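# Two-level Gaussian mixed models by maximum likelihood, with group-mean
# centering of level-1 predictors. Estimation is delegated to lme4 (ML,
# never REML, so likelihood-ratio tests across fixed-effect changes remain
# valid); the zero-random-effect case collapses to ordinary least squares.

#' Group-mean center a predictor
#'
#' Decomposes a level-1 predictor into its within component (deviation from
#' the cluster mean) and between component (the cluster mean), so each can
#' receive its own coefficient.
#'
#' @param table Data.frame.
#' @param predictor Name of a numeric column.
#' @param cluster Name of the clustering column.
#' @return Data.frame with columns \code{within} and \code{between}, one row
#'   per row of \code{table}.
#' @export
group_mean_center <- function(table, predictor, cluster) {
  x <- table[[predictor]]
  g <- table[[cluster]]
  if (is.null(x)) stop("no column ", sQuote(predictor), call. = FALSE)
  if (all(is.na(x))) {
    stop("predictor ", sQuote(predictor), " is entirely missing",
         call. = FALSE)
  }
  m <- stats::ave(x, g, FUN = function(v) mean(v, na.rm = TRUE))
  data.frame(within = x - m, between = m)
}

add_decomposition <- function(table, predictors, cluster) {
  for (p in predictors) {
    d <- group_mean_center(table, p, cluster)
    table[[paste0(p, "_w")]] <- d$within
    table[[paste0(p, "_b")]] <- d$between
  }
  table
}

#' Specify a two-level mixed model
#'
#' @param outcome Outcome column name.
#' @param within Character vector of level-1 (already centered) predictor
#'   columns.
#' @param between Character vector of cluster-level predictor columns
#'   (cluster means and country-level variables).
#' @param interactions List of length-2 character vectors
#'   \code{c(within_term, cluster_level_term)}; each within term must appear
#'   in \code{within}.
#' @param random_intercept Logical: include a random intercept by cluster?
#' @param random_slopes Character vector, subset of \code{within}, receiving
#'   random slopes.
#' @param cluster Clustering column name.
#' @param diagonal Logical: constrain random intercept/slope covariances to
#'   zero (the default) or estimate them freely.
#' @return Object of class \code{mixed_spec}.
#' @export
mixed_spec <- function(outcome, within = character(), between = character(),
                       interactions = list(), random_intercept = FALSE,
                       random_slopes = character(), cluster,
                       diagonal = TRUE) {
  if (length(random_slopes) && !all(random_slopes %in% within)) {
    stop("random slopes must be a subset of the within predictors",
         call. = FALSE)
  }
  for (ia in interactions) {
    if (length(ia) != 2L || !(ia[1] %in% within)) {
      stop("each interaction must pair a within predictor with a ",
           "cluster-level term", call. = FALSE)
    }
  }
  structure(list(outcome = outcome, within = within, between = between,
                 interactions = interactions,
                 random_intercept = random_intercept,
                 random_slopes = random_slopes, cluster = cluster,
                 diagonal = diagonal),
            class = "mixed_spec")
}

spec_formula <- function(spec) {
  fixed <- c(spec$within, spec$between,
             vapply(spec$interactions, function(ia) paste(ia, collapse = ":"),
                    character(1)))
  if (!length(fixed)) fixed <- "1"
  rhs <- paste(fixed, collapse = " + ")
  has_random <- spec$random_intercept || length(spec$random_slopes)
  if (has_random) {
    if (!length(spec$random_slopes)) {
      re <- paste0("(1 | ", spec$cluster, ")")
    } else {
      ic <- if (spec$random_intercept) "1" else "0"
      bar <- if (spec$diagonal) "||" else "|"
      re <- paste0("(", ic, " + ",
                   paste(spec$random_slopes, collapse = " + "), " ", bar,
                   " ", spec$cluster, ")")
    }
    rhs <- paste0(rhs, " + ", re)
  }
  stats::as.formula(paste(spec$outcome, "~", rhs))
}

check_rank <- function(spec, table) {
  fixed <- c(spec$within, spec$between,
             vapply(spec$interactions, function(ia) paste(ia, collapse = ":"),
                    character(1)))
  if (!length(fixed)) return(invisible(NULL))
  ff <- stats::as.formula(paste("~", paste(fixed, collapse = " + ")))
  X <- stats::model.matrix(ff, table)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    aliased <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("rank-deficient fixed-effect design; collinear column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  invisible(NULL)
}

#' Fit a two-level linear mixed model by maximum likelihood
#'
#' Maximizes the Gaussian marginal likelihood of
#' \eqn{y = X\beta + Zu + e}, \eqn{u \sim N(0, T)}, \eqn{e \sim N(0,
#' \sigma^2 I)} by ML (never REML). With no random terms the model is fitted
#' by ordinary least squares, whose ML log-likelihood is reported so nested
#' comparisons against mixed fits remain valid. Non-convergence is flagged,
#' never silent; a failed optimization is retried with an alternative
#' optimizer before being flagged.
#'
#' @param spec \code{\link{mixed_spec}} object.
#' @param table Data.frame holding every column the model spec names.
#' @return Object of class \code{mixed_fit}: \code{beta}, \code{se},
#'   \code{vcov}, \code{tau} (random-effect variances, plus covariances when
#'   estimated freely), \code{sigma2} (ML residual variance), \code{loglik},
#'   \code{n_obs}, \code{n_clusters}, \code{converged}.
#' @export
fit_mixed <- function(spec, table) {
  stopifnot(inherits(spec, "mixed_spec"))
  n_cl <- length(unique(table[[spec$cluster]]))
  if (n_cl < 2L) stop("need at least 2 clusters", call. = FALSE)
  check_rank(spec, table)
  form <- spec_formula(spec)
  has_random <- spec$random_intercept || length(spec$random_slopes)

  if (!has_random) {
    fit <- stats::lm(form, data = table)
    n <- length(stats::residuals(fit))
    out <- list(
      beta = stats::coef(fit),
      se = sqrt(diag(stats::vcov(fit))),
      vcov = stats::vcov(fit),
      tau = numeric(0),
      sigma2 = sum(stats::residuals(fit)^2) / n,
      loglik = as.numeric(stats::logLik(fit)),
      n_obs = n,
      n_clusters = n_cl,
      converged = TRUE,
      formula = form,
      engine = fit
    )
    class(out) <- "mixed_fit"
    return(out)
  }

  ctrl <- lme4::lmerControl(optimizer = "bobyqa",
                            calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  fit <- suppressMessages(lme4::lmer(form, data = table, REML = FALSE,
                                     control = ctrl))
  bad <- function(f) {
    length(f@optinfo$conv$lme4$messages) > 0 || f@optinfo$conv$opt != 0
  }
  if (bad(fit)) {
    ctrl2 <- lme4::lmerControl(optimizer = "Nelder_Mead",
                               check.conv.singular = "ignore")
    fit2 <- suppressMessages(suppressWarnings(
      lme4::lmer(form, data = table, REML = FALSE, control = ctrl2)))
    if (!bad(fit2) || stats::logLik(fit2) > stats::logLik(fit)) fit <- fit2
  }

  vc <- lme4::VarCorr(fit)
  tau <- c()
  for (grp in names(vc)) {
    v <- vc[[grp]]
    d <- diag(v)
    names(d) <- paste0("var_", rownames(v))
    names(d)[rownames(v) == "(Intercept)"] <- "var_intercept"
    tau <- c(tau, d)
    if (!spec$diagonal && nrow(v) > 1) {
      for (i in 2:nrow(v)) for (j in 1:(i - 1)) {
        tau <- c(tau, stats::setNames(v[i, j],
                                      paste0("cov_", rownames(v)[j], "_",
                                             rownames(v)[i])))
      }
    }
  }
  vcv <- as.matrix(stats::vcov(fit))
  out <- list(
    beta = lme4::fixef(fit),
    se = sqrt(diag(vcv)),
    vcov = vcv,
    tau = tau,
    sigma2 = stats::sigma(fit)^2,
    loglik = as.numeric(stats::logLik(fit)),
    n_obs = stats::nobs(fit),
    n_clusters = n_cl,
    converged = !bad(fit),
    formula = form,
    engine = fit
  )
  class(out) <- "mixed_fit"
  out
}

#' @export
print.mixed_fit <- function(x, digits = 4, ...) {
  cat("Two-level linear mixed model (ML)\n")
  cat(deparse(x$formula), "\n")
  cat(sprintf("n = %d observations in %d clusters; logLik = %.3f%s\n",
              x$n_obs, x$n_clusters, x$loglik,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  tab <- cbind(estimate = x$beta, se = x$se)
  print(round(tab, digits))
  if (length(x$tau)) {
    cat("Random effects (variances):\n")
    print(round(x$tau, digits + 2))
  }
  cat(sprintf("Residual variance (ML): %.*f\n", digits, x$sigma2))
  invisible(x)
}

#' Combine per-equation fits into one joint likelihood
#'
#' The mediator and outcome equations share no parameters and have
#' independent errors, so the joint log-likelihood of a model stage is the
#' sum of the equation log-likelihoods. The combined object can be passed to
#' \code{\link{lr_test}}.
#'
#' @param fits List of \code{mixed_fit} objects fitted on the same rows.
#' @return Object of class \code{mixed_fit_joint} with \code{loglik},
#'   \code{n_obs}, \code{converged}.
#' @export
joint_fit <- function(fits) {
  n <- unique(vapply(fits, function(f) f$n_obs, numeric(1)))
  if (length(n) != 1L) {
    stop("equations were fitted on different row counts", call. = FALSE)
  }
  structure(list(
    loglik = sum(vapply(fits, function(f) f$loglik, numeric(1))),
    n_obs = n,
    converged = all(vapply(fits, function(f) f$converged, logical(1)))
  ), class = "mixed_fit_joint")
}

#' Likelihood-ratio test between nested ML fits
#'
#' \eqn{\Delta\chi^2 = 2(\ell_{full} - \ell_{reduced})}, clamped at zero,
#' referred to the chi-square distribution with the supplied degrees of
#' freedom. The naive chi-square reference is used even when variance
#' components sit on the boundary (anti-conservative there).
#'
#' @param full,reduced Fits (\code{mixed_fit} or \code{mixed_fit_joint})
#'   estimated by ML on identical rows, \code{full} nesting \code{reduced}.
#' @param df Degrees of freedom (number of constrained parameters).
#' @return Object of class \code{lr_test_result}: \code{delta_chi2},
#'   \code{df}, \code{p_value}.
#' @export
lr_test <- function(full, reduced, df) {
  if (full$n_obs != reduced$n_obs) {
    stop("fits use different numbers of rows; likelihoods not comparable",
         call. = FALSE)
  }
  if (!isTRUE(full$converged) || !isTRUE(reduced$converged)) {
    stop("both fits must have converged", call. = FALSE)
  }
  delta <- max(0, 2 * (full$loglik - reduced$loglik))
  structure(list(delta_chi2 = delta, df = as.integer(df),
                 p_value = stats::pchisq(delta, df, lower.tail = FALSE)),
            class = "lr_test_result")
}

#' @export
print.lr_test_result <- function(x, ...) {
  cat(sprintf("LR test: delta chi-square = %.4f, df = %d, p = %.4g\n",
              x$delta_chi2, x$df, x$p_value))
  invisible(x)
}
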