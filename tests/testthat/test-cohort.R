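cal <- default_calendar()
cl <- test_codelists()

test_that("the 1-year registration run-in gates entry to the day", {
  p <- make_patient(reg_start = "2019-06-01", birth_year = 1979)  # aged 40
  wk <- eligible_weeks(p, make_events("P1", character(0), character(0)),
                       cohort_rule("anxiety", 11), cal)
  expect_equal(min(wk), as.Date("2020-06-07"))  # first week on/after 2020-06-01
  expect_equal(wk, seq(as.Date("2020-06-07"), as.Date("2020-07-12"), 7))
})

test_that("diabetes eligibility starts at the first diagnosis code", {
  p <- make_patient(reg_start = "2015-01-01", birth_year = 1970)
  ev <- make_events("P1", "2018-03-15", "DM1")
  rule <- cohort_rule("diabetic_emergency", 11, chronic_mode = "ever",
                      chronic_codelist = "diabetes")
  wk <- eligible_weeks(p, ev, rule, cal, cl)
  expect_equal(min(wk), as.Date("2018-03-18"))  # first week on/after the code
  expect_equal(max(wk), as.Date("2020-07-12"))
  expect_equal(length(wk), as.numeric(max(wk) - min(wk)) / 7 + 1)
})

asthma_rule <- cohort_rule("asthma_exacerbation", 11,
                           chronic_mode = "current_asthma",
                           chronic_codelist = "asthma",
                           copd_codelist = "copd")

test_that("asthma currency windows lapse and re-enter on later codes", {
  # adult: single code 2017-02-01 is current for 3 years at the week start
  p <- make_patient(birth_year = 1980, reg_start = "2010-01-01")
  wk <- eligible_weeks(p, make_events("P1", "2017-02-01", "AST1"),
                       asthma_rule, cal, cl)
  expect_equal(min(wk), as.Date("2017-02-05"))
  expect_equal(max(wk), as.Date("2020-01-26"))  # last week start < 2020-02-01

  # child (under 18 throughout): 2-year window
  pc <- make_patient(birth_year = 2003, reg_start = "2007-01-01")
  wkc <- eligible_weeks(pc, make_events("P1", "2017-02-01", "AST1"),
                        asthma_rule, cal, cl)
  expect_equal(max(wkc), as.Date("2019-01-27"))  # last week start < 2019-02-01

  # re-entry: a later code reopens eligibility after a lapse
  wk2 <- eligible_weeks(
    p, make_events("P1", c("2017-02-01", "2020-03-01"), "AST1"),
    asthma_rule, cal, cl)
  expect_true(as.Date("2020-03-01") %in% wk2)
  expect_equal(max(wk2), as.Date("2020-07-12"))
  gap <- seq(as.Date("2020-02-02"), as.Date("2020-02-23"), 7)
  expect_false(any(gap %in% wk2))
})

test_that("asthma at 40+ is reclassified to COPD by a subsequent COPD code", {
  p <- make_patient(birth_year = 1970, reg_start = "2010-01-01")  # aged 47+
  asthma <- make_events("P1", "2018-01-10", "AST1")
  copd_soon <- make_events("P1", "2019-06-01", "COPD1")
  copd_late <- make_events("P1", "2020-02-01", "COPD1")

  expect_gt(length(eligible_weeks(p, asthma, asthma_rule, cal, cl)), 0)
  # COPD within 2 years of the asthma record discounts it entirely
  expect_equal(length(eligible_weeks(p, dplyr::bind_rows(asthma, copd_soon),
                                     asthma_rule, cal, cl)), 0)
  # COPD more than 2 years later leaves the asthma record standing
  expect_gt(length(eligible_weeks(p, dplyr::bind_rows(asthma, copd_late),
                                  asthma_rule, cal, cl)), 0)
  # under 40 the reclassification never applies
  young <- make_patient(birth_year = 1990, reg_start = "2010-01-01")
  expect_gt(length(eligible_weeks(young, dplyr::bind_rows(asthma, copd_soon),
                                  asthma_rule, cal, cl)), 0)
})

test_that("COPD denominator needs diagnosis, smoking history and age 41+", {
  rule <- cohort_rule("copd_exacerbation", 41, chronic_mode = "ever",
                      chronic_codelist = "copd",
                      requires_smoking_history = TRUE,
                      smoking_codelist = "smoking")
  p <- make_patient(birth_year = 1960, reg_start = "2010-01-01")
  copd <- make_events("P1", "2017-06-01", "COPD1")
  smoke <- make_events("P1", "2018-02-04", "SMOK1")  # a Sunday week start
  expect_equal(length(eligible_weeks(p, copd, rule, cal, cl)), 0)
  wk <- eligible_weeks(p, dplyr::bind_rows(copd, smoke), rule, cal, cl)
  # smoking evidence must pre-date the week: entry the week after the code
  expect_equal(min(wk), as.Date("2018-02-11"))
})

test_that("death and deregistration end eligibility, never to resume", {
  p <- make_patient(reg_start = "2010-01-01", death = "2019-05-15",
                    birth_year = 1970)
  wk <- eligible_weeks(p, make_events("P1", character(0), character(0)),
                       cohort_rule("anxiety", 11), cal)
  expect_equal(max(wk), as.Date("2019-05-12"))  # dying mid-week still counts
  p2 <- make_patient(reg_start = "2010-01-01", reg_end = "2018-01-07",
                     birth_year = 1970)
  wk2 <- eligible_weeks(p2, make_events("P1", character(0), character(0)),
                        cohort_rule("anxiety", 11), cal)
  expect_equal(max(wk2), as.Date("2017-12-31"))  # no week begins on/after end
})

test_that("age bands migrate at the July-1 birthday convention", {
  p <- make_patient(birth_year = 1998, reg_start = "2010-01-01")
  den <- build_denominators(p, make_events("P1", character(0), character(0)),
                            cohort_rule("anxiety", 11), cal,
                            strata = "age_band")
  band <- den[den$stratifier == "age_band" & den$count == 1, ]
  b20 <- band$week_start[band$stratum == "11-20"]
  b30 <- band$week_start[band$stratum == "21-30"]
  expect_equal(max(b20), as.Date("2019-06-30"))
  expect_equal(min(b30), as.Date("2019-07-07"))  # first week aged 21
})

test_that("stratum counts partition the overall denominator", {
  cfg <- sim_config(n_patients = 400, registration_churn = 0.2,
                    death_rate = 0.05, seed = 31)
  pop <- simulate_population(cfg)
  ev <- simulate_chronic_events(pop, cfg)
  for (rule in list(cohort_rule("anxiety", 11),
                    cohort_rule("diabetic_emergency", 11,
                                chronic_mode = "ever",
                                chronic_codelist = "diabetes"))) {
    den <- build_denominators(pop, ev, rule, cal,
                              strata = c("age_band", "sex", "region",
                                         "ethnicity"), codelists = cl)
    overall <- den[den$stratifier == "overall", ]
    for (s in c("age_band", "sex", "region", "ethnicity")) {
      strat <- den[den$stratifier == s, ]
      sums <- stats::aggregate(count ~ week_start, strat, sum)
      expect_equal(sums$count[match(overall$week_start, sums$week_start)],
                   overall$count)
    }
    # no denominator exceeds the population size
    expect_true(all(overall$count <= nrow(pop)))
  }
})

test_that("eligibility respects run-in, death and deregistration in bulk", {
  cfg <- sim_config(n_patients = 300, registration_churn = 0.25,
                    death_rate = 0.08, seed = 13)
  pop <- simulate_population(cfg)
  elig <- eligibility_table(pop, make_events("x", character(0), character(0)),
                            cohort_rule("anxiety", 11), cal)
  idx <- match(elig$patient_id, pop$patient_id)
  expect_true(all(elig$week_start >=
                    lubridate::add_with_rollback(pop$registration_start[idx],
                                                 lubridate::years(1))))
  far <- as.Date("9999-01-01")
  expect_true(all(elig$week_start <
                    pmin(dplyr::coalesce(pop$death_date[idx], far),
                         dplyr::coalesce(pop$registration_end[idx], far))))
  expect_true(all(age_years(pop$birth_date[idx], elig$week_start) >= 11))
})

test_that("dropping the chronic requirement never shrinks a denominator", {
  cfg <- sim_config(n_patients = 300, seed = 17)
  pop <- simulate_population(cfg)
  ev <- simulate_chronic_events(pop, cfg)
  with_chronic <- build_denominators(
    pop, ev, cohort_rule("diabetic_emergency", 11, chronic_mode = "ever",
                         chronic_codelist = "diabetes"), cal, codelists = cl)
  without <- build_denominators(pop, ev, cohort_rule("diabetic_emergency", 11),
                                cal)
  expect_true(all(without$count >= with_chronic$count))
})

test_that("unknown stratifiers are rejected", {
  p <- make_patient()
  expect_error(build_denominators(p, make_events("P1", character(0),
                                                 character(0)),
                                  cohort_rule("anxiety", 11), cal,
                                  strata = "practice"), "practice")
})
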