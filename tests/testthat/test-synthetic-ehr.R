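test_that("population sampling honours degenerate and tabulated margins", {
  one_cat <- list(age_band = c(`31-40` = 1), sex = c(female = 1),
                  region = c(London = 1), ethnicity = c(White = 1))
  cfg <- sim_config(n_patients = 1, demographic_margins = one_cat, seed = 7)
  pop <- simulate_population(cfg)
  expect_equal(nrow(pop), 1)
  expect_equal(as.character(pop$sex), "female")
  expect_equal(as.character(pop$region), "London")
  expect_equal(as.character(pop$ethnicity), "White")
  expect_true(dplyr::between(2017 - lubridate::year(pop$birth_date), 31, 40))

  cfg <- sim_config(n_patients = 1e5, seed = 11)
  pop <- simulate_population(cfg)
  expect_equal(nrow(pop), 1e5)
  # female margin 0.4990 from the population table; 3 Monte-Carlo SDs
  target <- default_demographic_margins()$sex[["female"]]
  expect_lt(abs(mean(pop$sex == "female") - target),
            3 * sqrt(target * (1 - target) / 1e5))
  # every registration spell overlaps the calendar
  expect_true(all(pop$registration_start <= cfg$calendar_end))
  expect_true(all(is.na(pop$registration_end) |
                    pop$registration_end >= cfg$calendar_start))
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(n_patients = 200, ar_rho = 0.4, ar_sigma = 0.1,
                    step_log_or = log(0.5), seed = 99)
  expect_identical(simulate_population(cfg), simulate_population(cfg))
  expect_identical(simulate_weekly_counts(cfg), simulate_weekly_counts(cfg))
  e1 <- simulate_ehr(cfg)
  e2 <- simulate_ehr(cfg)
  expect_identical(e1$clinical_events, e2$clinical_events)
  expect_identical(e1$prescriptions, e2$prescriptions)
})

test_that("config validation names the offending field", {
  bad <- default_demographic_margins()
  bad$sex <- c(female = 0.6, male = 0.6)
  expect_error(sim_config(demographic_margins = bad), "sex")
  expect_error(sim_config(ar_rho = 1), "ar_rho")
  expect_error(sim_config(month_effects = rep(0.1, 12)), "January")
  expect_error(sim_config(restriction_week_start = "2021-06-06"),
               "calendar_start < restriction")
  expect_error(simulate_weekly_counts(sim_config(), n_weeks_pre = -1),
               "nonnegative")
  expect_error(simulate_weekly_counts(sim_config(), denominator = 0),
               "positive")
})

test_that("null and saturated contact processes behave as closed forms", {
  # effectively zero contact probability -> no events
  cfg <- sim_config(n_patients = 50, baseline_logit = -50, seed = 3)
  pop <- simulate_population(cfg)
  expect_equal(nrow(simulate_contact_events(pop, cfg)), 0)
  # p = 1, denominator 1 -> count 1 every week
  sat <- simulate_weekly_counts(sim_config(baseline_logit = 50, seed = 3),
                                denominator = 1)
  expect_true(all(sat$count == 1))
})

test_that("aggregated mode lays out the 166+16 week grid", {
  s <- simulate_weekly_counts(sim_config(seed = 5))
  expect_equal(nrow(s), 182)
  expect_equal(s$week_start[1], as.Date("2017-01-01"))
  expect_equal(s$week_start[166], as.Date("2020-03-01"))
  expect_equal(s$week_start[167], as.Date("2020-03-29"))
  expect_equal(s$week_start[182], as.Date("2020-07-12"))
  # the three adjustment weeks carry no rows
  expect_false(any(s$week_start %in% as.Date(c("2020-03-08", "2020-03-15",
                                               "2020-03-22"))))
})

test_that("weekly proportions match the oracle mean without noise", {
  p0 <- 0.01
  n <- 1e5
  n_in_band <- 0
  n_weeks <- 0
  for (seed in 1:5) {
    cfg <- sim_config(baseline_logit = qlogis(p0), seed = seed)
    s <- simulate_weekly_counts(cfg, denominator = n)
    expect_equal(s$p, rep(p0, nrow(s)))   # oracle is exact with ar_sigma = 0
    band <- 3 * sqrt(p0 * (1 - p0) / n)
    n_in_band <- n_in_band + sum(abs(s$proportion - p0) <= band)
    n_weeks <- n_weeks + nrow(s)
  }
  expect_gte(n_in_band / n_weeks, 0.99)
})

test_that("a generating step moves post/pre odds by the configured ratio", {
  or_true <- 0.35
  ests <- vapply(1:8, function(seed) {
    cfg <- sim_config(baseline_logit = qlogis(0.002),
                      step_log_or = log(or_true), seed = seed)
    s <- simulate_weekly_counts(cfg, denominator = 1e6)
    post <- s$week_start >= cfg$restriction_week_start
    odds <- function(x) mean(x) / (1 - mean(x))
    odds(s$proportion[post]) / odds(s$proportion[!post])
  }, numeric(1))
  expect_lt(abs(mean(ests) - or_true), 3 * sd(ests) / sqrt(length(ests)))
})

test_that("individual-record contacts respect registration and dates", {
  cfg <- sim_config(n_patients = 120, baseline_logit = qlogis(0.05),
                    registration_churn = 0.3, death_rate = 0.05, seed = 21)
  pop <- simulate_population(cfg)
  ev <- simulate_contact_events(pop, cfg)
  truth <- attr(ev, "truth")
  expect_equal(nrow(truth), 185)
  expect_named(truth, c("week_start", "eta", "p"))
  idx <- match(ev$patient_id, pop$patient_id)
  expect_true(all(ev$event_date >= pop$registration_start[idx]))
  wk <- floor_week(ev$event_date)
  end <- pmin(dplyr::coalesce(pop$registration_end[idx], as.Date("9999-01-01")),
              dplyr::coalesce(pop$death_date[idx], as.Date("9999-01-01")))
  expect_true(all(wk < end))
  # at most one contact per person-week
  expect_false(any(duplicated(data.frame(ev$patient_id, wk))))
})

test_that("CSV export writes the four ISO-dated tables", {
  cfg <- sim_config(n_patients = 30, baseline_logit = qlogis(0.05), seed = 2)
  dir <- withr::local_tempdir()
  write_ehr_csv(simulate_ehr(cfg), dir)
  files <- c("patients.csv", "clinical_events.csv", "prescriptions.csv",
             "weekly_truth.csv")
  expect_true(all(file.exists(file.path(dir, files))))
  ev <- utils::read.csv(file.path(dir, "clinical_events.csv"))
  expect_true(all(grepl("^\\d{4}-\\d{2}-\\d{2}$", ev$event_date)))
})
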