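#' Configure the synthetic EHR generator
#'
#' The generator draws a registered population with demographic margins and
#' chronic-condition prevalences, then simulates weekly primary-care contact
#' indicators from a logistic model with a linear time trend, calendar-month
#' seasonality, a step change and a recovery slope at a configurable
#' restriction date, and optional AR(1) noise on the logit scale:
#'
#' \deqn{\eta_t = \alpha + \beta_1 t + s_{month(t)} +
#'   I(t \ge t_0)\,(\gamma + \delta (t - t_0)) + \varepsilon_t}
#'
#' with \eqn{P(\text{contact}) = \mathrm{logit}^{-1}(\eta_t)} per person-week,
#' at most one contact per person-week. The true \eqn{\eta_t} and
#' \eqn{p_t} are exposed alongside every simulated dataset, so model code can
#' be tested against known generating values.
#'
#' @param n_patients Number of patients (individual-record mode).
#' @param calendar_start,calendar_end Study calendar bounds;
#'   `calendar_start` must lie on the Sunday week grid.
#' @param restriction_week_start Sunday starting the first with-restrictions
#'   week (default March 29 2020).
#' @param baseline_logit Log-odds of at least one contact per person-week in
#'   the reference month at `calendar_start`.
#' @param trend_per_week Linear log-odds drift per week.
#' @param month_effects Numeric length-12 log-odds offsets by calendar month;
#'   January is the reference and must be 0.
#' @param step_log_or Log odds ratio of the step change at
#'   `restriction_week_start`.
#' @param slope_log_or_per_week Log odds ratio per week of the recovery slope
#'   after `restriction_week_start`.
#' @param ar_rho,ar_sigma AR(1) noise on the logit scale: autocorrelation in
#'   (-1, 1) and innovation standard deviation (0 disables noise). The
#'   process starts from its stationary distribution.
#' @param demographic_margins Named list of named probability vectors for
#'   `age_band`, `sex`, `region`, `ethnicity`; each must sum to 1.
#' @param chronic_prevalence Named probabilities for `diabetes`, `asthma`,
#'   `copd`, `smoking` status.
#' @param registration_churn Annual deregistration probability.
#' @param death_rate Annual death probability.
#' @param contact_code,chronic_codes,prescription_code Opaque codes used in
#'   the emitted tables; codelists used downstream must share this namespace.
#' @param rx_prob Probability that a contact is accompanied by a same-day
#'   prescription row (for exercising composite exacerbation rules).
#' @param seed Integer seed; all `simulate_*()` functions are deterministic
#'   given the config.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_patients = 1000,
                       calendar_start = study_start(),
                       calendar_end = study_end_date(),
                       restriction_week_start = as.Date("2020-03-29"),
                       baseline_logit = stats::qlogis(0.002),
                       trend_per_week = 0,
                       month_effects = rep(0, 12),
                       step_log_or = 0,
                       slope_log_or_per_week = 0,
                       ar_rho = 0,
                       ar_sigma = 0,
                       demographic_margins = default_demographic_margins(),
                       chronic_prevalence = default_chronic_prevalence(),
                       registration_churn = 0.05,
                       death_rate = 0.01,
                       contact_code = "CONTACT1",
                       chronic_codes = c(diabetes = "DM1", asthma = "AST1",
                                         copd = "COPD1", smoking = "SMOK1"),
                       prescription_code = "RX1",
                       rx_prob = 0.8,
                       seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    calendar_start = as_date_scalar(calendar_start, "calendar_start"),
    calendar_end = as_date_scalar(calendar_end, "calendar_end"),
    restriction_week_start = as_date_scalar(restriction_week_start,
                                            "restriction_week_start"),
    baseline_logit = as.numeric(baseline_logit),
    trend_per_week = as.numeric(trend_per_week),
    month_effects = as.numeric(month_effects),
    step_log_or = as.numeric(step_log_or),
    slope_log_or_per_week = as.numeric(slope_log_or_per_week),
    ar_rho = as.numeric(ar_rho),
    ar_sigma = as.numeric(ar_sigma),
    demographic_margins = demographic_margins,
    chronic_prevalence = chronic_prevalence,
    registration_churn = as.numeric(registration_churn),
    death_rate = as.numeric(death_rate),
    contact_code = contact_code,
    chronic_codes = chronic_codes,
    prescription_code = prescription_code,
    rx_prob = as.numeric(rx_prob),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (is.na(cfg$n_patients) || cfg$n_patients < 1) {
    stop("`n_patients` must be a positive integer", call. = FALSE)
  }
  if (!(cfg$calendar_start < cfg$restriction_week_start &&
        cfg$restriction_week_start < cfg$calendar_end)) {
    stop("need calendar_start < restriction_week_start < calendar_end",
         call. = FALSE)
  }
  if (!is_on_week_grid(cfg$calendar_start) ||
      !is_on_week_grid(cfg$restriction_week_start)) {
    stop("calendar_start and restriction_week_start must lie on the Sunday ",
         "week grid", call. = FALSE)
  }
  if (length(cfg$month_effects) != 12) {
    stop("`month_effects` must have length 12", call. = FALSE)
  }
  if (abs(cfg$month_effects[1]) > 1e-12) {
    stop("`month_effects` must have January (element 1) fixed at 0",
         call. = FALSE)
  }
  if (!(cfg$ar_rho > -1 && cfg$ar_rho < 1)) {
    stop("`ar_rho` must lie strictly inside (-1, 1)", call. = FALSE)
  }
  if (cfg$ar_sigma < 0) stop("`ar_sigma` must be nonnegative", call. = FALSE)
  for (m in names(cfg$demographic_margins)) {
    p <- cfg$demographic_margins[[m]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop("demographic margin '", m, "' must be nonnegative and sum to 1 ",
           "(observed sum ", format(sum(p), digits = 12), ")", call. = FALSE)
    }
  }
  probs <- c(unlist(cfg$chronic_prevalence), cfg$registration_churn,
             cfg$death_rate, cfg$rx_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Default demographic margins
#'
#' Category probabilities for age band, sex, region and ethnicity matching
#' the 2017 composition of a UK-wide primary-care denominator population of
#' about 9.9 million (11 regions; ethnicity including a large Missing
#' category reflecting real recording gaps).
#'
#' @return Named list of named probability vectors.
#' @export
default_demographic_margins <- function() {
  norm <- function(x) x / sum(x)
  list(
    age_band = norm(c(`11-20` = 1233387, `21-30` = 1455550, `31-40` = 1559933,
                      `41-50` = 1577507, `51-60` = 1520720, `61-70` = 1165390,
                      `71-80` = 833570, `81-90` = 426769, `91-100` = 91077)),
    sex = norm(c(female = 4921693, male = 4942210)),
    region = norm(c(`North East` = 343510, `North West` = 1690063,
                    `Yorkshire and the Humber` = 371809,
                    `East Midlands` = 259468, `West Midlands` = 1571832,
                    `East of England` = 464376, `South West` = 1185045,
                    `South Central` = 1242192, London = 1842724,
                    `South East Coast` = 827239, `Northern Ireland` = 47713)),
    ethnicity = norm(c(White = 4814510, `South Asian` = 425917,
                       Black = 261552, Other = 147583, Mixed = 94174,
                       Missing = 4120167))
  )
}

#' @rdname default_demographic_margins
#' @export
default_chronic_prevalence <- function() {
  c(diabetes = 0.07, asthma = 0.09, copd = 0.045, smoking = 0.25)
}

# Run code with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Deterministic part of the contact-generating process
#'
#' @param config A [sim_config()].
#' @param week_start Dates on the week grid.
#' @return Numeric log-odds \eqn{\eta_t} without AR(1) noise.
#' @export
contact_eta <- function(config, week_start) {
  week_start <- as.Date(week_start)
  t <- as.numeric(week_start - config$calendar_start) / 7
  tsr <- as.numeric(week_start - config$restriction_week_start) / 7
  post <- as.numeric(week_start >= config$restriction_week_start)
  config$baseline_logit +
    config$trend_per_week * t +
    config$month_effects[as.integer(lubridate::month(week_start))] +
    post * (config$step_log_or + config$slope_log_or_per_week * tsr)
}

# AR(1) logit noise over n consecutive weeks, stationary initialisation.
ar1_noise <- function(n, rho, sigma) {
  if (sigma == 0 || n == 0) return(rep(0, n))
  eps <- numeric(n)
  eps[1] <- stats::rnorm(1, 0, sigma / sqrt(1 - rho^2))
  if (n > 1) {
    innov <- stats::rnorm(n - 1, 0, sigma)
    for (i in 2:n) eps[i] <- rho * eps[i - 1] + innov[i - 1]
  }
  eps
}

#' Simulate a registered patient population
#'
#' Draws demographics from the configured margins, a registration spell
#' overlapping the study calendar (with annual deregistration churn), and a
#' possible in-study death. Birth dates carry year resolution only and are
#' materialised as July 1 of the birth year, mirroring de-identified EHR
#' precision; ages downstream are computed against that convention.
#'
#' @param config A [sim_config()].
#' @return A tibble of patients: `patient_id`, `birth_date`, `sex`, `region`,
#'   `ethnicity`, `registration_start`, `registration_end` (NA while open),
#'   `death_date` (NA if alive), plus logical chronic-status columns
#'   `diabetes`, `asthma`, `copd`, `smoking` used to seed dated diagnosis
#'   codes.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_patients
  m <- config$demographic_margins
  with_seed(config$seed, {
    draw <- function(margin) {
      factor(sample(names(margin), n, replace = TRUE, prob = margin),
             levels = names(margin))
    }
    age_band <- draw(m$age_band)
    band_lo <- as.integer(sub("-.*", "", as.character(age_band)))
    band_hi <- as.integer(sub(".*-", "", as.character(age_band)))
    age <- band_lo + floor(stats::runif(n) * (band_hi - band_lo + 1))
    birth_year <- lubridate::year(config$calendar_start) - age
    birth_date <- as.Date(paste0(birth_year, "-07-01"))

    old_reg <- stats::runif(n) < 0.85
    reg_start <- dplyr::if_else(
      old_reg,
      config$calendar_start - floor(stats::runif(n, 0, 15 * 365.25)),
      config$calendar_start +
        floor(stats::runif(n) *
                as.numeric(config$calendar_end - 7 - config$calendar_start))
    )
    reg_start <- pmax(reg_start, birth_date)

    # deregistration hazard applies over the in-study exposure window
    churn_days <- stats::rexp(n, rate = max(config$registration_churn, 1e-12) / 365.25)
    reg_end <- pmax(reg_start, config$calendar_start) + ceiling(churn_days)
    reg_end[config$registration_churn == 0 | reg_end > config$calendar_end] <- NA

    death_days <- stats::rexp(n, rate = max(config$death_rate, 1e-12) / 365.25)
    death <- config$calendar_start + ceiling(death_days)
    death[config$death_rate == 0 | death > config$calendar_end] <- NA

    chronic <- purrr::map(config$chronic_prevalence,
                          ~ stats::runif(n) < .x)

    tibble::tibble(
      patient_id = sprintf("P%06d", seq_len(n)),
      birth_date = birth_date,
      sex = draw(m$sex),
      region = draw(m$region),
      ethnicity = draw(m$ethnicity),
      registration_start = reg_start,
      registration_end = reg_end,
      death_date = death,
      diabetes = chronic$diabetes,
      asthma = chronic$asthma,
      copd = chronic$copd,
      smoking = chronic$smoking
    )
  })
}

#' Simulate dated chronic-condition diagnosis codes
#'
#' Each patient flagged with a chronic status receives one dated diagnosis
#' code: at registration with probability 0.7 (prevalent at entry), else at
#' an onset date drawn uniformly between registration and the calendar end.
#' This exercises denominator-entry logic keyed on the first record of a
#' diagnosis.
#'
#' @param patients Output of [simulate_population()].
#' @param config The same [sim_config()].
#' @return A tibble of `ClinicalEvent` rows: `patient_id`, `event_date`,
#'   `code`, `source`.
#' @export
simulate_chronic_events <- function(patients, config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 1L, {
    purrr::map_dfr(names(config$chronic_codes), function(cond) {
      has <- patients[[cond]]
      if (!any(has)) return(NULL)
      p <- patients[has, ]
      at_reg <- stats::runif(nrow(p)) < 0.7
      span <- as.numeric(config$calendar_end - p$registration_start)
      onset <- p$registration_start +
        floor(stats::runif(nrow(p)) * pmax(span, 1))
      tibble::tibble(
        patient_id = p$patient_id,
        event_date = dplyr::if_else(at_reg, p$registration_start, onset),
        code = unname(config$chronic_codes[[cond]]),
        source = "diagnosis"
      )
    })
  })
}

#' Simulate weekly contact events for a population
#'
#' For every week in which a patient is registered (and alive at the week
#' start), draws a Bernoulli contact indicator with probability
#' \eqn{\mathrm{logit}^{-1}(\eta_t)}; a drawn contact becomes one clinical
#' event with the configured contact code, dated uniformly within the week.
#' At most one contact per person-week is emitted, matching the
#' "proportion of the population with contacts" outcome the downstream
#' models fit.
#'
#' @param patients Output of [simulate_population()].
#' @param config The same [sim_config()].
#' @return A tibble of contact `ClinicalEvent` rows with a `truth` attribute:
#'   a tibble (`week_start`, `eta`, `p`) of the realised generating process
#'   (including AR(1) noise).
#' @export
simulate_contact_events <- function(patients, config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(patients) == 0) stop("`patients` must be non-empty", call. = FALSE)
  grid <- week_grid(config$calendar_start, config$calendar_end)
  with_seed(config$seed + 2L, {
    eps <- ar1_noise(nrow(grid), config$ar_rho, config$ar_sigma)
    eta <- contact_eta(config, grid$week_start) + eps
    p <- stats::plogis(eta)
    truth <- tibble::tibble(week_start = grid$week_start, eta = eta, p = p)

    nw <- nrow(grid)
    np <- nrow(patients)
    week_start <- rep(grid$week_start, times = np)
    pat_idx <- rep(seq_len(np), each = nw)
    end <- pmin(
      dplyr::coalesce(patients$registration_end[pat_idx],
                      as.Date("9999-01-01")),
      dplyr::coalesce(patients$death_date[pat_idx], as.Date("9999-01-01"))
    )
    active <- week_start >= patients$registration_start[pat_idx] &
      week_start < end
    hit <- active & stats::runif(length(week_start)) < p[rep(seq_len(nw), np)]
    events <- tibble::tibble(
      patient_id = patients$patient_id[pat_idx[hit]],
      event_date = week_start[hit] + floor(stats::runif(sum(hit)) * 7),
      code = config$contact_code,
      source = "diagnosis"
    )
    events <- dplyr::arrange(events, .data$patient_id, .data$event_date)
    attr(events, "truth") <- truth
    events
  })
}

#' Simulate aggregated weekly contact counts
#'
#' Fast mode bypassing individual records: weekly counts are drawn directly
#' as Binomial(denominator, \eqn{p_t}) under the configured generating
#' process. The emitted table covers `n_weeks_pre` weeks from
#' `calendar_start` plus `n_weeks_post` weeks from `restriction_week_start`;
#' the adjustment gap between the two segments carries no rows (it is
#' excluded from model fitting anyway) but the AR(1) noise is iterated
#' across it, so autocorrelation bridges the gap exactly as the fitted
#' model's lagged residuals do.
#'
#' @param config A [sim_config()].
#' @param n_weeks_pre,n_weeks_post Number of pre-interruption and
#'   with-restrictions weeks (defaults 166 and 16, the default study grid).
#' @param denominator Constant weekly denominator.
#' @return A `WeeklySeries` tibble: `week_start`, `count`, `denominator`,
#'   `proportion`, plus truth columns `eta` and `p`.
#' @export
simulate_weekly_counts <- function(config, n_weeks_pre = 166L,
                                   n_weeks_post = 16L, denominator = 1e6) {
  stopifnot(inherits(config, "sim_config"))
  n_weeks_pre <- as.integer(n_weeks_pre)
  n_weeks_post <- as.integer(n_weeks_post)
  if (is.na(n_weeks_pre) || is.na(n_weeks_post) ||
      n_weeks_pre < 0 || n_weeks_post < 0) {
    stop("week counts must be nonnegative integers", call. = FALSE)
  }
  if (denominator < 1) stop("`denominator` must be positive", call. = FALSE)
  last_pre <- config$calendar_start + (n_weeks_pre - 1) * 7
  if (n_weeks_pre > 0 && last_pre >= config$restriction_week_start) {
    stop("`n_weeks_pre` runs past the restriction start", call. = FALSE)
  }
  last_post <- config$restriction_week_start + (n_weeks_post - 1) * 7
  grid <- week_grid(config$calendar_start, max(last_pre, last_post) + 6)
  keep <- grid$week_start <= last_pre |
    (n_weeks_post > 0 & grid$week_start >= config$restriction_week_start &
       grid$week_start <= last_post)
  with_seed(config$seed, {
    eps <- ar1_noise(nrow(grid), config$ar_rho, config$ar_sigma)
    eta <- contact_eta(config, grid$week_start) + eps
    p <- stats::plogis(eta)
    counts <- stats::rbinom(nrow(grid), size = as.integer(denominator), prob = p)
    tibble::tibble(
      week_start = grid$week_start,
      count = counts,
      denominator = as.integer(denominator),
      proportion = counts / denominator,
      eta = eta,
      p = p
    )[keep, ]
  })
}

#' Simulate a full synthetic EHR bundle
#'
#' Composes [simulate_population()], [simulate_chronic_events()] and
#' [simulate_contact_events()], splitting prescription rows (a same-day
#' prescription accompanies each contact with probability `rx_prob`) into
#' their own table as real extracts do.
#'
#' @param config A [sim_config()].
#' @return A list with tibbles `patients`, `clinical_events`,
#'   `prescriptions`, and `truth` (week_start, eta, p).
#' @export
simulate_ehr <- function(config) {
  patients <- simulate_population(config)
  chronic <- simulate_chronic_events(patients, config)
  contacts <- simulate_contact_events(patients, config)
  truth <- attr(contacts, "truth")
  rx <- with_seed(config$seed + 3L, {
    take <- stats::runif(nrow(contacts)) < config$rx_prob
    tibble::tibble(
      patient_id = contacts$patient_id[take],
      event_date = contacts$event_date[take],
      code = config$prescription_code,
      source = "prescription"
    )
  })
  clinical <- dplyr::arrange(
    dplyr::bind_rows(chronic, contacts),
    .data$patient_id, .data$event_date, .data$code
  )
  attr(clinical, "truth") <- NULL
  list(patients = patients, clinical_events = clinical,
       prescriptions = rx, truth = truth)
}

#' Write a synthetic EHR bundle to CSV
#'
#' Emits `patients.csv`, `clinical_events.csv`, `prescriptions.csv` and
#' `weekly_truth.csv` with ISO-8601 dates.
#'
#' @param ehr Output of [simulate_ehr()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ehr_csv <- function(ehr, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(ehr$patients, file.path(dir, "patients.csv"),
                   row.names = FALSE)
  utils::write.csv(ehr$clinical_events, file.path(dir, "clinical_events.csv"),
                   row.names = FALSE)
  utils::write.csv(ehr$prescriptions, file.path(dir, "prescriptions.csv"),
                   row.names = FALSE)
  utils::write.csv(ehr$truth, file.path(dir, "weekly_truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}
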