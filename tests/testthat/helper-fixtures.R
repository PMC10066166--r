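# Programmatic fixtures shared across tests.

# Small law/policy table: 4 countries, itemized protections across domains.
fixture_laws <- function() {
  rows <- list(
    # AA: well protected on both variants
    c("AA", "equality_nondiscrimination", "eq1", "national", "sexual_orientation"),
    c("AA", "family", "fam1", "national", "sexual_orientation"),
    c("AA", "hate_crime_speech", "hc1", "national", "sexual_orientation"),
    c("AA", "asylum", "as1", "regional", "sexual_orientation"),
    c("AA", "equality_nondiscrimination", "eq2", "national", "gender_identity"),
    c("AA", "legal_gender_recognition_bodily_integrity", "lgr1", "national", "gender_identity"),
    # BB: 3 national + 1 regional sexual-orientation items (points 3.5)
    c("BB", "equality_nondiscrimination", "eq1", "national", "sexual_orientation"),
    c("BB", "family", "fam1", "national", "sexual_orientation"),
    c("BB", "hate_crime_speech", "hc1", "national", "sexual_orientation"),
    c("BB", "civil_society", "cs1", "regional", "sexual_orientation"),
    c("BB", "legal_gender_recognition_bodily_integrity", "lgr1", "regional", "gender_identity"),
    # CC: one regional item only
    c("CC", "equality_nondiscrimination", "eq1", "regional", "sexual_orientation"),
    c("CC", "equality_nondiscrimination", "eq2", "absent", "gender_identity"),
    # DD: nothing protective
    c("DD", "equality_nondiscrimination", "eq1", "absent", "sexual_orientation"),
    c("DD", "equality_nondiscrimination", "eq2", "absent", "gender_identity")
  )
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- c("country_code", "domain", "item_id", "status", "applies_to")
  out
}

fixture_attitudes <- function() {
  data.frame(
    country_code = rep(c("AA", "BB", "CC", "DD"), 2),
    target = rep(c("sexual_minorities", "gender_minorities"), each = 4),
    mean_comfort = c(8.6, 7.1, 4.2, 2.9, 7.9, 6.4, 3.8, 2.5),
    stringsAsFactors = FALSE
  )
}

fixture_covariates <- function() {
  data.frame(
    country_code = c("AA", "BB", "CC", "DD"),
    gdp_ppp = c(55000, 48000, 31000, 24000),
    democracy_index = c(9.0, 8.1, 6.9, 6.2),
    hdi = c(0.94, 0.92, 0.86, 0.82),
    stringsAsFactors = FALSE
  )
}

# Larger 8-country law/attitude/covariate tables for end-to-end runs, where
# the country-level design (stigma + three covariates) needs more clusters
# than the 4-country golden fixture provides.
bundle_laws <- function() {
  countries <- paste0(LETTERS[1:8], LETTERS[1:8])
  doms <- c("equality_nondiscrimination", "family", "hate_crime_speech",
            "civil_society", "asylum")
  statuses <- c("national", "regional", "absent")
  rows <- list()
  for (i in seq_along(countries)) {
    for (d in seq_along(doms)) {
      for (v in c("sexual_orientation", "gender_identity")) {
        rows[[length(rows) + 1]] <- data.frame(
          country_code = countries[i], domain = doms[d],
          item_id = paste0(doms[d], "_", substr(v, 1, 2)),
          status = statuses[1 + (i * 2 + d + (v == "gender_identity")) %% 3],
          applies_to = v, stringsAsFactors = FALSE)
      }
    }
    rows[[length(rows) + 1]] <- data.frame(
      country_code = countries[i],
      domain = "legal_gender_recognition_bodily_integrity",
      item_id = "lgr", status = statuses[1 + i %% 3],
      applies_to = "gender_identity", stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

bundle_attitudes <- function() {
  countries <- paste0(LETTERS[1:8], LETTERS[1:8])
  data.frame(
    country_code = rep(countries, 2),
    target = rep(c("sexual_minorities", "gender_minorities"), each = 8),
    mean_comfort = c(8.7, 3.1, 6.4, 4.9, 7.8, 2.6, 5.5, 9.2,
                     7.9, 2.8, 5.9, 4.1, 7.1, 2.2, 5.0, 8.6),
    stringsAsFactors = FALSE
  )
}

bundle_covariates <- function() {
  data.frame(
    country_code = paste0(LETTERS[1:8], LETTERS[1:8]),
    gdp_ppp = c(55, 24, 41, 33, 52, 27, 38, 61) * 1000,
    democracy_index = c(9.0, 6.1, 7.7, 8.3, 6.8, 7.2, 8.9, 7.4),
    hdi = c(0.94, 0.82, 0.89, 0.91, 0.85, 0.88, 0.83, 0.93),
    stringsAsFactors = FALSE
  )
}

# One raw respondent row with sensible defaults, overridable per field.
raw_row <- function(...) {
  base <- list(
    country_code = "AA", gender_item = "man", trans_history = FALSE,
    sexual_orientation = "gay",
    cp_active = TRUE, cp_contact = FALSE, cp_follow = TRUE,
    cp_financial = FALSE,
    victimization_category = "never",
    disclosure_family = "a_few", disclosure_friends = "most",
    disclosure_neighbours = "none", disclosure_colleagues = "a_few",
    disclosure_schoolmates = "not_applicable", disclosure_superior = "a_few",
    disclosure_customers = "not_applicable", disclosure_medical = "most",
    depression_category = "some of the time",
    age_years = 30L, ethnic_minority = FALSE, income_band = "middle_to_high"
  )
  over <- list(...)
  base[names(over)] <- over
  as.data.frame(base, stringsAsFactors = FALSE)
}

raw_table <- function(rows) do.call(rbind, rows)

# Coded records spanning the 4 fixture countries for analysis-table tests.
fixture_records <- function(n = 40, seed = 42) {
  set.seed(seed)
  data.frame(
    country = sample(c("AA", "BB", "CC", "DD"), n, replace = TRUE),
    subgroup = sample(c("sexual_minority_men", "sexual_minority_women",
                        "gender_minority"), n, replace = TRUE),
    cp = sample(c(0, 0.25, 0.5, 0.75, 1), n, replace = TRUE),
    disclosure = round(runif(n, 0, 3), 2),
    victim_freq = sample(c(0L, 1L, 2L, 4L), n, replace = TRUE),
    victimization = NA_integer_,
    depression = sample(0:5, n, replace = TRUE),
    age_years = sample(18:70, n, replace = TRUE),
    ethnic_minority = rbinom(n, 1, 0.1),
    income_level = sample(1:6, n, replace = TRUE),
    stringsAsFactors = FALSE
  ) -> rec
  rec$victimization <- as.integer(rec$victim_freq > 0)
  rec
}

fixture_stigma_table <- function() {
  build_stigma_table(fixture_laws(), fixture_attitudes(),
                     fixture_covariates())
}

# Balanced one-way random-intercept data for the closed-form check.
balanced_ri_data <- function(J = 5, n = 20, mu = 2, tau = 0.8, sigma = 1.2,
                             seed = 7) {
  set.seed(seed)
  g <- rep(seq_len(J), each = n)
  u <- rnorm(J, 0, tau)
  data.frame(g = factor(g), y = mu + u[g] + rnorm(J * n, 0, sigma))
}
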