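# Composite country-level structural-stigma index: itemized protective
# laws/policies (1 point national, 0.5 regional) summed per country, z-scored,
# averaged with z-scored mean public attitudes, then sign-inverted so higher
# scores mean more structural stigma.

policy_domains <- function() {
  c("equality_nondiscrimination", "family", "hate_crime_speech",
    "civil_society", "asylum", "legal_gender_recognition_bodily_integrity")
}

#' Score the protective law/policy index
#'
#' Sums protective-policy points per country: 1 for national/federal
#' application, 0.5 for regional-only application, 0 for absent. The
#' sexual-orientation variant covers five domains; the gender-identity
#' variant additionally includes the legal-gender-recognition and bodily-
#' integrity domain, which applies to gender minorities only.
#'
#' @param laws Data.frame with columns \code{country_code}, \code{domain},
#'   \code{item_id}, \code{status} (\code{national}, \code{regional},
#'   \code{absent}), \code{applies_to} (\code{sexual_orientation},
#'   \code{gender_identity}).
#' @param variant \code{"so"} (sexual orientation) or \code{"gi"}
#'   (gender identity).
#' @return Named numeric vector of raw points per country, covering every
#'   country present in \code{laws}.
#' @export
score_policy_index <- function(laws, variant = c("so", "gi")) {
  variant <- match.arg(variant)
  if (!nrow(laws)) stop("law/policy table is empty", call. = FALSE)
  dup <- duplicated(laws[, c("country_code", "item_id")])
  if (any(dup)) {
    d <- laws[dup, c("country_code", "item_id")]
    stop("duplicate (country, item) pair(s): ",
         paste(paste0(d$country_code, "/", d$item_id), collapse = ", "),
         call. = FALSE)
  }
  bad_dom <- setdiff(unique(laws$domain), policy_domains())
  if (length(bad_dom)) {
    stop("unknown policy domain(s): ", paste(bad_dom, collapse = ", "),
         call. = FALSE)
  }
  gi_only <- "legal_gender_recognition_bodily_integrity"
  if (any(laws$domain == gi_only & laws$applies_to != "gender_identity")) {
    stop("legal gender recognition / bodily integrity items must have ",
         "applies_to = gender_identity", call. = FALSE)
  }
  target <- if (variant == "so") "sexual_orientation" else "gender_identity"
  sel <- laws$applies_to == target
  points <- c(national = 1, regional = 0.5, absent = 0)
  bad_status <- setdiff(unique(laws$status), names(points))
  if (length(bad_status)) {
    stop("unknown status value(s): ", paste(bad_status, collapse = ", "),
         call. = FALSE)
  }
  countries <- sort(unique(laws$country_code))
  pts <- tapply(points[laws$status[sel]], laws$country_code[sel], sum)
  out <- stats::setNames(numeric(length(countries)), countries)
  out[names(pts)] <- pts
  out
}

#' Standardize per-country scores
#'
#' z-scores with the sample (n-1) standard deviation, the package default
#' for country-level composites.
#'
#' @param values Named numeric vector (one value per country).
#' @return Named numeric vector with mean 0 and sd 1.
#' @export
standardize <- function(values) {
  if (length(values) < 2L) {
    stop("standardization requires at least 2 countries", call. = FALSE)
  }
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) {
    stop("zero dispersion: the composite is undefined", call. = FALSE)
  }
  (values - mean(values)) / s
}

#' Compose the structural-stigma score
#'
#' Averages the standardized policy index and standardized attitude score
#' and inverts the sign, so that higher values mean more structural stigma
#' (fewer protections, less positive attitudes).
#'
#' @param policy_z,attitude_z Named numeric vectors of z-scores over the
#'   same country set.
#' @return Named numeric vector of composite scores.
#' @export
compose_stigma <- function(policy_z, attitude_z) {
  only_p <- setdiff(names(policy_z), names(attitude_z))
  only_a <- setdiff(names(attitude_z), names(policy_z))
  if (length(only_p) || length(only_a)) {
    stop("country sets differ; only in policy: {",
         paste(only_p, collapse = ", "), "}; only in attitudes: {",
         paste(only_a, collapse = ", "), "}", call. = FALSE)
  }
  attitude_z <- attitude_z[names(policy_z)]
  -(policy_z + attitude_z) / 2
}

#' Build the per-country structural-stigma table
#'
#' Runs the full composite construction for both variants: policy points are
#' summed (\code{\link{score_policy_index}}), standardized over the set of
#' countries in the input, averaged with the standardized mean attitude
#' score for the matching target population, and sign-inverted. Country
#' covariates are joined. A provenance attribute records item counts per
#' domain per country.
#'
#' @param laws Law/policy table (see \code{\link{score_policy_index}}).
#' @param attitudes Data.frame with columns \code{country_code},
#'   \code{target} (\code{sexual_minorities} or \code{gender_minorities}),
#'   \code{mean_comfort} (1-10, higher = more positive).
#' @param covariates Data.frame with columns \code{country_code},
#'   \code{gdp_ppp}, \code{democracy_index}, \code{hdi}.
#' @return Data.frame of class \code{stigma_table} with columns
#'   \code{country}, \code{so_stigma}, \code{gi_stigma}, \code{gdp_ppp},
#'   \code{democracy_index}, \code{hdi}.
#' @export
build_stigma_table <- function(laws, attitudes, covariates) {
  if (any(attitudes$mean_comfort < 1 | attitudes$mean_comfort > 10,
          na.rm = TRUE)) {
    stop("mean_comfort must lie on the 1-10 scale", call. = FALSE)
  }
  variant_score <- function(variant, target) {
    pol <- score_policy_index(laws, variant)
    att <- attitudes[attitudes$target == target, ]
    att_v <- stats::setNames(att$mean_comfort, att$country_code)
    compose_stigma(standardize(pol), standardize(att_v))
  }
  so <- variant_score("so", "sexual_minorities")
  gi <- variant_score("gi", "gender_minorities")
  countries <- names(so)
  idx <- match(countries, covariates$country_code)
  if (anyNA(idx)) {
    stop("covariates missing for: ",
         paste(countries[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    country = countries,
    so_stigma = unname(so),
    gi_stigma = unname(gi[countries]),
    gdp_ppp = covariates$gdp_ppp[idx],
    democracy_index = covariates$democracy_index[idx],
    hdi = covariates$hdi[idx],
    stringsAsFactors = FALSE
  )
  class(out) <- c("stigma_table", "data.frame")
  attr(out, "provenance") <- list(
    n_items = nrow(laws),
    items_per_domain_country = as.list(table(laws$domain, laws$country_code))
  )
  out
}
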