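# Coding of raw survey items into analysis variables.

#' Victimization frequency codes
#'
#' Named integer vector mapping the seven ordered frequency labels for
#' physical or sexual attacks in the last five years to their numeric codes.
#' The non-linear spacing reflects the category midpoints of the original
#' response options.
#'
#' @format Named integer vector of length 7.
#' @export
victimization_codes <- c(
  "never" = 0L,
  "once" = 1L,
  "twice" = 2L,
  "3-5 times" = 4L,
  "6-10 times" = 8L,
  "more than 10 times" = 11L,
  "all the time" = 15L
)

#' Depression frequency codes
#'
#' Named integer vector mapping the six ordered labels of the single-item
#' depressed-mood question ("Have you been feeling downhearted or depressed
#' over the last 2 weeks?") to ordinal codes 0-5.
#'
#' @format Named integer vector of length 6.
#' @export
depression_codes <- c(
  "at no time" = 0L,
  "some of the time" = 1L,
  "less than half of the time" = 2L,
  "more than half of the time" = 3L,
  "most of the time" = 4L,
  "all the time" = 5L
)

#' Identity disclosure item codes
#'
#' Named integer vector mapping the per-target openness labels to codes 0-3;
#' "not_applicable" carries no code and is excluded from the mean.
#'
#' @format Named integer vector of length 4.
#' @export
disclosure_codes <- c(
  "none" = 0L,
  "a_few" = 1L,
  "most" = 2L,
  "all" = 3L
)

#' Income band codes
#'
#' Named integer vector mapping the six ordered income bands to 1-6, used as
#' a numeric covariate.
#'
#' @format Named integer vector of length 6.
#' @export
income_codes <- c(
  "very_low" = 1L,
  "low" = 2L,
  "low_to_middle" = 3L,
  "middle_to_high" = 4L,
  "high" = 5L,
  "very_high" = 6L
)

# en/em dashes in exported label sets are normalized to ASCII hyphens
normalize_label <- function(x) {
  x <- gsub("–|—", "-", x)
  trimws(tolower(x))
}

map_labels <- function(x, codes, what) {
  x <- normalize_label(as.character(x))
  out <- unname(codes[x])
  bad <- !is.na(x) & x != "" & is.na(out)
  if (any(bad)) {
    stop(sprintf("unknown %s label(s): %s", what,
                 paste(sQuote(unique(x[bad])), collapse = ", ")),
         call. = FALSE)
  }
  out[is.na(x) | x == ""] <- NA_integer_
  out
}

#' Classify respondents into analysis subgroups
#'
#' Applies the two-step gender-identity classification followed by sexual
#' orientation: a current trans or non-binary identity, or an affirmative
#' trans-history answer, yields \code{"gender_minority"}; remaining
#' heterosexual respondents are excluded; remaining respondents are split
#' into sexual minority men and women by gender item. Respondents under 18
#' are excluded. Records missing both classification questions are flagged
#' \code{"unclassifiable"}.
#'
#' @param gender_item Character vector with values in \code{woman, man,
#'   trans_woman, trans_man, nonbinary_plus, other}.
#' @param sexual_orientation Character vector with values in \code{lesbian,
#'   gay, bisexual, heterosexual, other, dont_know}.
#' @param trans_history Logical vector: has the respondent ever been a trans
#'   person? Consulted only for non-trans \code{gender_item} values.
#' @param age_years Integer vector of ages.
#' @return Character vector with values in \code{sexual_minority_men,
#'   sexual_minority_women, gender_minority, excluded, unclassifiable}.
#' @export
classify_subgroup <- function(gender_item, sexual_orientation,
                              trans_history = NA, age_years = NA) {
  n <- max(length(gender_item), length(sexual_orientation))
  gender_item <- rep_len(normalize_label(as.character(gender_item)), n)
  sexual_orientation <- rep_len(normalize_label(as.character(sexual_orientation)), n)
  trans_history <- rep_len(trans_history, n)
  age_years <- rep_len(age_years, n)

  gender_levels <- c("woman", "man", "trans_woman", "trans_man",
                     "nonbinary_plus", "other")
  so_levels <- c("lesbian", "gay", "bisexual", "heterosexual", "other",
                 "dont_know")
  chk_g <- !is.na(gender_item) & gender_item != "" & !(gender_item %in% gender_levels)
  chk_s <- !is.na(sexual_orientation) & sexual_orientation != "" &
    !(sexual_orientation %in% so_levels)
  if (any(chk_g)) {
    stop("unknown gender_item label(s): ",
         paste(sQuote(unique(gender_item[chk_g])), collapse = ", "),
         call. = FALSE)
  }
  if (any(chk_s)) {
    stop("unknown sexual_orientation label(s): ",
         paste(sQuote(unique(sexual_orientation[chk_s])), collapse = ", "),
         call. = FALSE)
  }
  g_missing <- is.na(gender_item) | gender_item == ""
  s_missing <- is.na(sexual_orientation) | sexual_orientation == ""

  out <- rep(NA_character_, n)
  out[g_missing & s_missing] <- "unclassifiable"
  gm <- !g_missing &
    (gender_item %in% c("trans_woman", "trans_man", "nonbinary_plus", "other") |
       (!is.na(trans_history) & trans_history))
  out[is.na(out) & gm] <- "gender_minority"
  het <- !s_missing & sexual_orientation == "heterosexual"
  out[is.na(out) & het] <- "excluded"
  out[is.na(out) & !g_missing & gender_item == "man"] <- "sexual_minority_men"
  out[is.na(out) & !g_missing & gender_item == "woman"] <- "sexual_minority_women"
  out[is.na(out)] <- "unclassifiable"
  out[!is.na(age_years) & age_years < 18] <- "excluded"
  out
}

#' Code community participation
#'
#' Mean of four 0/1 involvement items (active member/volunteer, regular
#' contact, follows activities, financial supporter), giving a score on the
#' five-point grid 0, 0.25, 0.5, 0.75, 1.
#'
#' @param cp_items Logical matrix or data.frame with four columns (or a
#'   length-4 logical vector for a single respondent).
#' @return Numeric vector of participation scores in \[0, 1\].
#' @export
code_community_participation <- function(cp_items) {
  if (is.null(dim(cp_items))) cp_items <- matrix(cp_items, nrow = 1)
  cp_items <- as.matrix(cp_items)
  if (ncol(cp_items) != 4L) {
    stop("community participation requires exactly 4 items", call. = FALSE)
  }
  storage.mode(cp_items) <- "double"
  rowMeans(cp_items)
}

#' Code victimization frequency
#'
#' Maps the seven ordered frequency labels to integer codes
#' (see \code{\link{victimization_codes}}). Unknown labels are an error.
#'
#' @param category Character vector of frequency labels.
#' @return Integer vector of codes in \code{0, 1, 2, 4, 8, 11, 15}.
#' @export
code_victimization <- function(category) {
  map_labels(category, victimization_codes, "victimization")
}

#' Dichotomize a victimization frequency code
#'
#' 0 for no victimization (code 0), 1 for at least one victimization
#' (any positive code).
#'
#' @param code Integer vector of frequency codes.
#' @return Integer 0/1 vector.
#' @export
dichotomize_victimization <- function(code) {
  ok <- is.na(code) | code %in% unname(victimization_codes)
  if (!all(ok)) {
    stop("unmapped victimization code(s): ",
         paste(unique(code[!ok]), collapse = ", "), call. = FALSE)
  }
  as.integer(code > 0)
}

#' Code identity disclosure
#'
#' Mean of the 0-3 openness codes over the disclosure targets that apply to
#' the respondent (family, friends, neighbours, colleagues, schoolmates,
#' superior, customers, medical staff). When none of the eight groups
#' applies the score is missing, not an error.
#'
#' @param items Character matrix or data.frame with eight columns of labels
#'   in \code{none, a_few, most, all, not_applicable} (or a length-8 vector
#'   for a single respondent).
#' @return Numeric vector in \[0, 3\], \code{NA} where no group applies.
#' @export
code_disclosure <- function(items) {
  if (is.null(dim(items))) items <- matrix(items, nrow = 1)
  items <- as.matrix(items)
  if (ncol(items) != 8L) {
    stop("identity disclosure requires exactly 8 items", call. = FALSE)
  }
  lab <- normalize_label(items)
  dim(lab) <- dim(items)
  applicable <- !is.na(lab) & lab != "not_applicable" & lab != ""
  known <- lab %in% c(names(disclosure_codes), "not_applicable", "", NA)
  if (!all(known | is.na(lab))) {
    stop("unknown disclosure label(s): ",
         paste(sQuote(unique(lab[!known])), collapse = ", "), call. = FALSE)
  }
  num <- matrix(unname(disclosure_codes[lab]), nrow = nrow(items))
  num[!applicable] <- NA_real_
  n_app <- rowSums(applicable)
  out <- rowSums(num, na.rm = TRUE) / n_app
  out[n_app == 0] <- NA_real_
  out
}

#' Code depression
#'
#' Maps the six ordered labels of the single-item depressed-mood question to
#' codes 0-5 (see \code{\link{depression_codes}}).
#'
#' @param category Character vector of labels.
#' @return Integer vector in 0..5.
#' @export
code_depression <- function(category) {
  map_labels(category, depression_codes, "depression")
}

#' Code a raw respondent table
#'
#' Applies every item-coding rule to a raw survey table and classifies each
#' respondent into a subgroup, producing one coded record per respondent and
#' a coding report (exclusion counts per rule, missingness per column).
#'
#' @param raw Data.frame with columns \code{country_code}, \code{gender_item},
#'   \code{trans_history}, \code{sexual_orientation}, \code{cp_active},
#'   \code{cp_contact}, \code{cp_follow}, \code{cp_financial},
#'   \code{victimization_category}, \code{disclosure_family},
#'   \code{disclosure_friends}, \code{disclosure_neighbours},
#'   \code{disclosure_colleagues}, \code{disclosure_schoolmates},
#'   \code{disclosure_superior}, \code{disclosure_customers},
#'   \code{disclosure_medical}, \code{depression_category},
#'   \code{age_years}, \code{ethnic_minority}, \code{income_band}.
#' @return List with \code{records} (coded data.frame with columns
#'   \code{country}, \code{subgroup}, \code{cp}, \code{disclosure},
#'   \code{victim_freq}, \code{victimization}, \code{depression},
#'   \code{age_years}, \code{ethnic_minority}, \code{income_level}) and
#'   \code{report} (a list of counts).
#' @export
code_survey_data <- function(raw) {
  needed <- c("country_code", "gender_item", "sexual_orientation",
              "cp_active", "cp_contact", "cp_follow", "cp_financial",
              "victimization_category", disclosure_columns(),
              "depression_category", "age_years", "ethnic_minority",
              "income_band")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    stop("raw survey table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  trans_history <- if ("trans_history" %in% names(raw)) {
    as.logical(raw$trans_history)
  } else NA

  subgroup <- classify_subgroup(raw$gender_item, raw$sexual_orientation,
                                trans_history, raw$age_years)
  vf <- code_victimization(raw$victimization_category)
  rec <- data.frame(
    country = as.character(raw$country_code),
    subgroup = subgroup,
    cp = code_community_participation(
      raw[, c("cp_active", "cp_contact", "cp_follow", "cp_financial")]),
    disclosure = code_disclosure(raw[, disclosure_columns()]),
    victim_freq = vf,
    victimization = dichotomize_victimization(vf),
    depression = code_depression(raw$depression_category),
    age_years = as.integer(raw$age_years),
    ethnic_minority = as.integer(as.logical(raw$ethnic_minority)),
    income_level = map_labels(raw$income_band, income_codes, "income band"),
    stringsAsFactors = FALSE
  )
  keep <- !(rec$subgroup %in% c("excluded", "unclassifiable"))
  report <- list(
    n_raw = nrow(raw),
    n_excluded_heterosexual = sum(subgroup == "excluded" &
                                    !is.na(raw$age_years) & raw$age_years >= 18),
    n_excluded_under18 = sum(!is.na(raw$age_years) & raw$age_years < 18),
    n_unclassifiable = sum(subgroup == "unclassifiable"),
    n_retained = sum(keep),
    subgroup_counts = as.list(table(rec$subgroup[keep])),
    missing_per_column = lapply(rec[keep, , drop = FALSE],
                                function(x) sum(is.na(x)))
  )
  list(records = rec[keep, , drop = FALSE], report = report)
}

disclosure_columns <- function() {
  paste0("disclosure_", c("family", "friends", "neighbours", "colleagues",
                          "schoolmates", "superior", "customers", "medical"))
}

#' Assemble a per-subgroup analysis table
#'
#' Filters coded records to one subgroup, joins the matching structural
#' stigma variant (sexual-orientation scores for the sexual minority
#' subgroups, gender-identity scores for gender minorities) and the
#' country-level covariates, and applies listwise deletion on all model
#' variables. Row and deletion counts are attached as attributes.
#'
#' @param records Coded respondent data.frame (see
#'   \code{\link{code_survey_data}}).
#' @param subgroup One of \code{"sexual_minority_men"},
#'   \code{"sexual_minority_women"}, \code{"gender_minority"}.
#' @param stigma \code{stigma_table} data.frame with columns
#'   \code{country}, \code{so_stigma}, \code{gi_stigma}, \code{gdp_ppp},
#'   \code{democracy_index}, \code{hdi}.
#' @return Data.frame with the model variables plus a \code{stigma} column,
#'   attributes \code{n_input}, \code{n_dropped}.
#' @export
build_analysis_table <- function(records, subgroup, stigma) {
  subgroup <- match.arg(subgroup, c("sexual_minority_men",
                                    "sexual_minority_women",
                                    "gender_minority"))
  sub <- records[records$subgroup == subgroup, , drop = FALSE]
  missing_countries <- setdiff(unique(sub$country), stigma$country)
  if (length(missing_countries)) {
    stop("countries absent from the stigma table: ",
         paste(missing_countries, collapse = ", "), call. = FALSE)
  }
  stigma_col <- if (subgroup == "gender_minority") "gi_stigma" else "so_stigma"
  idx <- match(sub$country, stigma$country)
  sub$stigma <- stigma[[stigma_col]][idx]
  sub$gdp_ppp <- stigma$gdp_ppp[idx]
  sub$democracy_index <- stigma$democracy_index[idx]
  sub$hdi <- stigma$hdi[idx]

  model_vars <- c("cp", "disclosure", "victimization", "depression",
                  "age_years", "ethnic_minority", "income_level", "stigma",
                  "gdp_ppp", "democracy_index", "hdi")
  complete <- stats::complete.cases(sub[, model_vars, drop = FALSE])
  out <- sub[complete, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_input") <- nrow(sub)
  attr(out, "n_dropped") <- sum(!complete)
  out
}
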