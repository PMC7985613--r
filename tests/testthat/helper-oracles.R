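# Independent oracles and small fixture builders shared across tests.

# Exhaustive episode partition: merge records into episodes until fixpoint of
# the "within window of any record already in the episode's chain" relation,
# i.e. the transitive closure of consecutive-gap <= window. Deliberately
# different in shape from the greedy implementation under test.
dedup_oracle <- function(dates, window_days) {
  dates <- sort(as.Date(dates))
  n <- length(dates)
  if (n == 0) return(dates)
  group <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)[seq_len(max(n - 1, 0))]) {
      if (as.numeric(dates[i + 1] - dates[i]) <= window_days &&
          group[i + 1] != group[i]) {
        group[group == group[i + 1]] <- group[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  starts <- vapply(unique(group),
                   function(g) min(as.numeric(dates[group == g])),
                   numeric(1))
  sort(as.Date(starts, origin = "1970-01-01"))
}

random_date_set <- function(n_max = 30, span_days = 1500,
                            origin = as.Date("2017-01-01")) {
  n <- sample(0:n_max, 1)
  sort(origin + sample.int(span_days, n, replace = TRUE))
}

# Minimal patient row in the layout simulate_population() produces.
make_patient <- function(id = "P1", birth_year = 1980,
                         reg_start = "2010-01-01", reg_end = NA,
                         death = NA, sex = "female", region = "London",
                         ethnicity = "White") {
  tibble::tibble(
    patient_id = id,
    birth_date = as.Date(paste0(birth_year, "-07-01")),
    sex = sex, region = region, ethnicity = ethnicity,
    registration_start = as.Date(reg_start),
    registration_end = as.Date(reg_end),
    death_date = as.Date(death),
    diabetes = FALSE, asthma = FALSE, copd = FALSE, smoking = FALSE
  )
}

make_events <- function(id, dates, code) {
  tibble::tibble(patient_id = id, event_date = as.Date(dates),
                 code = code, source = "diagnosis")
}

test_codelists <- function() {
  as_codelists(tibble::tibble(
    list_name = c("diabetes", "asthma", "copd", "smoking", "heart_failure",
                  "anxiety", "oral_corticosteroid", "antibiotic"),
    kind = c(rep("morbidity", 6), "prescription", "prescription"),
    code = c("DM1", "AST1", "COPD1", "SMOK1", "HF1", "ANX1", "OCS1", "ABX1")
  ))
}

default_calendar <- function() week_grid()

# Deterministic two-level series on the full default grid: exact binomial
# means (integer counts), a pure step at the restriction date.
two_level_series <- function(p_pre = 0.02, p_post = 0.01, denominator = 1e6,
                             restriction = as.Date("2020-03-29")) {
  cal <- week_grid()
  p <- ifelse(cal$week_start >= restriction, p_post, p_pre)
  tibble::tibble(
    week_start = cal$week_start,
    count = as.integer(round(denominator * p)),
    denominator = as.integer(denominator),
    proportion = count / denominator
  )
}

null_sim_config <- function(seed, ar_rho = 0, ar_sigma = 0.05) {
  sim_config(baseline_logit = stats::qlogis(0.0025),
             month_effects = seasonal_month_effects(0.1),
             ar_rho = ar_rho, ar_sigma = ar_sigma, seed = seed)
}
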