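test_that("subgroup classification follows the two-step gender/orientation rules", {
  # trans or non-binary current identity -> gender minority, any orientation
  expect_equal(classify_subgroup("trans_woman", "heterosexual", FALSE, 30),
               "gender_minority")
  expect_equal(classify_subgroup("nonbinary_plus", "bisexual", NA, 25),
               "gender_minority")
  # trans history overrides a cisgender current identity
  expect_equal(classify_subgroup("woman", "heterosexual", TRUE, 40),
               "gender_minority")
  # cis heterosexual respondents are excluded
  expect_equal(classify_subgroup("man", "heterosexual", FALSE, 30),
               "excluded")
  # remaining respondents split by gender item
  expect_equal(classify_subgroup("man", "gay", FALSE, 30),
               "sexual_minority_men")
  expect_equal(classify_subgroup("woman", "lesbian", FALSE, 30),
               "sexual_minority_women")
  # minors are excluded regardless of identity
  expect_equal(classify_subgroup("man", "gay", FALSE, 17), "excluded")
  # missing both classification questions -> flagged, not guessed
  expect_equal(classify_subgroup(NA, NA, NA, 30), "unclassifiable")
  expect_error(classify_subgroup("male", "gay", FALSE, 30), "gender_item")
})

test_that("item coding reproduces every printed mapping", {
  # participation: mean of four 0/1 items, on the 5-point grid
  expect_equal(code_community_participation(c(TRUE, FALSE, TRUE, FALSE)), 0.5)
  expect_equal(code_community_participation(c(FALSE, FALSE, FALSE, FALSE)), 0)
  expect_equal(code_community_participation(c(TRUE, TRUE, TRUE, TRUE)), 1)

  # victimization frequency codes, including the non-linear spacing
  labels <- c("never", "once", "twice", "3-5 times", "6-10 times",
              "more than 10 times", "all the time")
  expect_equal(code_victimization(labels), c(0L, 1L, 2L, 4L, 8L, 11L, 15L))
  expect_equal(code_victimization("3–5 times"), 4L) # en-dash dialect
  expect_error(code_victimization("sometimes"), "victimization")

  # dichotomization: 0 iff never
  expect_equal(dichotomize_victimization(c(0L, 1L, 2L, 4L, 8L, 11L, 15L)),
               c(0L, rep(1L, 6)))
  expect_error(dichotomize_victimization(3L), "unmapped")

  # depression 0-5
  expect_equal(
    code_depression(c("at no time", "some of the time",
                      "less than half of the time",
                      "more than half of the time", "most of the time",
                      "all the time")),
    0:5)
  expect_error(code_depression("often"), "depression")
})

test_that("disclosure averages over applicable groups and is missing when none apply", {
  items <- c("a_few", "most", rep("not_applicable", 6))
  expect_equal(code_disclosure(items), 1.5)
  expect_equal(code_disclosure(rep("all", 8)), 3)
  expect_true(is.na(code_disclosure(rep("not_applicable", 8))))
  expect_error(code_disclosure(rep("plenty", 8)), "disclosure")
})

test_that("coded labels round-trip through their mapping tables", {
  # re-coding the label of every code reproduces the code exactly
  for (codes in list(victimization_codes, depression_codes,
                     disclosure_codes, income_codes)) {
    expect_identical(unname(codes[names(codes)]), unname(codes))
  }
  labs <- names(victimization_codes)[match(c(0L, 4L, 15L),
                                           victimization_codes)]
  expect_equal(code_victimization(labs), c(0L, 4L, 15L))
})

test_that("code_survey_data codes a table end-to-end and partitions subgroups", {
  raw <- raw_table(list(
    raw_row(),
    raw_row(gender_item = "woman", sexual_orientation = "bisexual",
            country_code = "BB"),
    raw_row(gender_item = "trans_man", sexual_orientation = "other"),
    raw_row(sexual_orientation = "heterosexual"),
    raw_row(age_years = 16L),
    raw_row(gender_item = NA, sexual_orientation = NA)
  ))
  out <- code_survey_data(raw)
  expect_equal(nrow(out$records), 3)
  expect_setequal(out$records$subgroup,
                  c("sexual_minority_men", "sexual_minority_women",
                    "gender_minority"))
  expect_equal(out$report$n_excluded_under18, 1)
  expect_equal(out$report$n_unclassifiable, 1)
  expect_true(all(out$records$cp %in% c(0, 0.25, 0.5, 0.75, 1)))
  expect_true(all(out$records$depression %in% 0:5))
  expect_true(all(out$records$victimization == (out$records$victim_freq > 0)))
})

test_that("analysis tables join the right stigma variant and delete listwise", {
  rec <- fixture_records()
  st <- fixture_stigma_table()

  men <- build_analysis_table(rec, "sexual_minority_men", st)
  expect_equal(men$stigma,
               st$so_stigma[match(men$country, st$country)])
  gm <- build_analysis_table(rec, "gender_minority", st)
  expect_equal(gm$stigma, st$gi_stigma[match(gm$country, st$country)])

  # listwise deletion drops exactly the incomplete rows
  rec2 <- rec
  rec2$income_level[rec2$subgroup == "sexual_minority_men"][1] <- NA
  men2 <- build_analysis_table(rec2, "sexual_minority_men", st)
  expect_equal(nrow(men2), nrow(men) - 1)
  expect_equal(attr(men2, "n_dropped"), 1)
  expect_false(anyNA(men2[, c("cp", "disclosure", "victimization",
                              "depression", "income_level", "stigma")]))

  # a country absent from the stigma table is a hard error naming it
  rec3 <- rec
  rec3$country[1] <- "ZZ"
  rec3$subgroup[1] <- "sexual_minority_men"
  expect_error(build_analysis_table(rec3, "sexual_minority_men", st), "ZZ")

  # degenerate input: empty subgroup keeps the schema
  none <- build_analysis_table(rec[0, ], "sexual_minority_men", st)
  expect_equal(nrow(none), 0)
  expect_true(all(c("cp", "stigma", "gdp_ppp") %in% names(none)))
})
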