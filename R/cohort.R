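#' Define a condition's denominator rule
#'
#' A cohort rule says who counts in a condition's weekly denominator: a
#' minimum age, a 1-year registration run-in, and (for chronic-disease
#' denominators) entry from the first dated diagnosis code, a currency
#' window for asthma, and a smoking-history requirement for COPD.
#'
#' @param condition Condition name.
#' @param min_age_years Minimum age (completed years) at the week start.
#' @param chronic_mode `"none"` (whole registered population), `"ever"`
#'   (eligible from the first record of the chronic codelist onwards), or
#'   `"current_asthma"` (eligible while an asthma code is current: within
#'   the past 2 years if aged under 18, 3 years otherwise, with re-entry on
#'   a later code).
#' @param chronic_codelist Codelist name carrying the chronic diagnosis
#'   codes (required unless `chronic_mode = "none"`).
#' @param asthma_window_child_years,asthma_window_adult_years Currency
#'   windows for `"current_asthma"`.
#' @param copd_reclass_window_years Asthma records in patients aged 40 or
#'   over are discounted if a COPD code follows within this many years
#'   (reclassification to COPD); requires `copd_codelist`.
#' @param copd_codelist Codelist name used for the reclassification check.
#' @param requires_smoking_history If `TRUE`, eligibility additionally
#'   requires any code from `smoking_codelist` dated strictly before the
#'   week under evaluation.
#' @param smoking_codelist Codelist name for smoking-history codes.
#' @param registration_run_in_years Registration run-in (default 1 year).
#' @return A `cohort_rule` list.
#' @export
cohort_rule <- function(condition,
                        min_age_years = 11L,
                        chronic_mode = c("none", "ever", "current_asthma"),
                        chronic_codelist = NULL,
                        asthma_window_child_years = 2L,
                        asthma_window_adult_years = 3L,
                        copd_reclass_window_years = 2L,
                        copd_codelist = NULL,
                        requires_smoking_history = FALSE,
                        smoking_codelist = NULL,
                        registration_run_in_years = 1L) {
  chronic_mode <- match.arg(chronic_mode)
  if (chronic_mode != "none" && is.null(chronic_codelist)) {
    stop("`chronic_codelist` is required when chronic_mode != 'none'",
         call. = FALSE)
  }
  if (requires_smoking_history && is.null(smoking_codelist)) {
    stop("`smoking_codelist` is required with requires_smoking_history",
         call. = FALSE)
  }
  stopifnot(min_age_years >= 0, registration_run_in_years >= 0,
            asthma_window_child_years > 0, asthma_window_adult_years > 0,
            copd_reclass_window_years > 0)
  structure(list(
    condition = condition,
    min_age_years = as.integer(min_age_years),
    chronic_mode = chronic_mode,
    chronic_codelist = chronic_codelist,
    asthma_window_child_years = as.integer(asthma_window_child_years),
    asthma_window_adult_years = as.integer(asthma_window_adult_years),
    copd_reclass_window_years = as.integer(copd_reclass_window_years),
    copd_codelist = copd_codelist,
    requires_smoking_history = requires_smoking_history,
    smoking_codelist = smoking_codelist,
    registration_run_in_years = as.integer(registration_run_in_years)
  ), class = "cohort_rule")
}

#' Age in completed years
#'
#' @param birth_date,at Date vectors (recycled).
#' @return Integer completed years between `birth_date` and `at`.
#' @export
age_years <- function(birth_date, at) {
  floor(lubridate::time_length(
    lubridate::interval(as.Date(birth_date), as.Date(at)), "years"))
}

add_years <- function(date, years) {
  lubridate::add_with_rollback(as.Date(date), lubridate::years(years))
}

#' Weekly eligibility for a denominator rule
#'
#' Evaluates every patient against a [cohort_rule()] at each week start of
#' the calendar. A week is included iff, at its start, the patient meets the
#' age minimum, has at least the run-in period of registration, is not dead
#' or deregistered (no eligible week begins on or after `death_date` or
#' `registration_end`), and meets the chronic-condition criterion.
#' Asthma-style currency eligibility can lapse and restart on a later code.
#'
#' @param patients Patient tibble (as from [simulate_population()]).
#' @param events Clinical event tibble (`patient_id`, `event_date`, `code`);
#'   only needed for chronic/smoking criteria.
#' @param rule A [cohort_rule()].
#' @param calendar A [week_grid()] tibble.
#' @param codelists Codelist tibble resolving the rule's codelist names.
#' @return A tibble (`patient_id`, `week_start`) of eligible person-weeks.
#' @export
eligibility_table <- function(patients, events, rule, calendar,
                              codelists = NULL) {
  stopifnot(inherits(rule, "cohort_rule"))
  weeks <- calendar$week_start
  far_future <- as.Date("9999-01-01")

  start_at <- pmax(
    add_years(patients$birth_date, rule$min_age_years),
    add_years(patients$registration_start, rule$registration_run_in_years)
  )
  end_excl <- pmin(
    dplyr::coalesce(patients$registration_end, far_future),
    dplyr::coalesce(patients$death_date, far_future)
  )

  first_code_by_patient <- function(list_name) {
    codes <- codelist_codes(codelists, list_name)
    hits <- events[events$code %in% codes, c("patient_id", "event_date")]
    if (nrow(hits) == 0) {
      return(tibble::tibble(patient_id = character(0),
                            first_date = as.Date(character(0))))
    }
    dplyr::summarise(dplyr::group_by(hits, .data$patient_id),
                     first_date = min(.data$event_date), .groups = "drop")
  }

  if (rule$chronic_mode == "ever") {
    first <- first_code_by_patient(rule$chronic_codelist)
    idx <- match(patients$patient_id, first$patient_id)
    start_at <- pmax(start_at,
                     dplyr::coalesce(first$first_date[idx], far_future))
  }
  if (rule$requires_smoking_history) {
    first <- first_code_by_patient(rule$smoking_codelist)
    idx <- match(patients$patient_id, first$patient_id)
    # smoking evidence must pre-date the week under evaluation
    start_at <- pmax(start_at,
                     dplyr::coalesce(first$first_date[idx], far_future) + 1)
  }

  np <- length(start_at)
  nw <- length(weeks)
  ws <- rep(weeks, times = np)
  pi <- rep(seq_len(np), each = nw)
  ok <- ws >= start_at[pi] & ws < end_excl[pi]

  if (rule$chronic_mode == "current_asthma") {
    codes <- codelist_codes(codelists, rule$chronic_codelist)
    asthma <- events[events$code %in% codes, c("patient_id", "event_date")]
    if (!is.null(rule$copd_codelist) &&
        rule$copd_codelist %in% codelists$list_name) {
      copd_codes <- codelists$code[codelists$list_name == rule$copd_codelist]
      copd <- events[events$code %in% copd_codes, c("patient_id", "event_date")]
      asthma <- discount_reclassified_asthma(asthma, copd, patients, rule)
    }
    ok <- ok & asthma_current_at(asthma, patients, pi, ws, rule)
  }

  tibble::tibble(patient_id = patients$patient_id[pi], week_start = ws)[ok, ]
}

# Drop asthma records in patients aged >= 40 at the record that are followed
# by a COPD code within the reclassification window (computed retrospectively
# over the full record, since the rule looks forward in time).
discount_reclassified_asthma <- function(asthma, copd, patients, rule) {
  if (nrow(asthma) == 0 || nrow(copd) == 0) return(asthma)
  birth <- patients$birth_date[match(asthma$patient_id, patients$patient_id)]
  at_risk <- age_years(birth, asthma$event_date) >= 40
  horizon <- add_years(asthma$event_date, rule$copd_reclass_window_years)
  reclass <- purrr::map_lgl(seq_len(nrow(asthma)), function(i) {
    if (!at_risk[i]) return(FALSE)
    cd <- copd$event_date[copd$patient_id == asthma$patient_id[i]]
    any(cd > asthma$event_date[i] & cd <= horizon[i])
  })
  asthma[!reclass, ]
}

# For each person-week, is the most recent remaining asthma code strictly
# within the age-appropriate currency window at the week start?
asthma_current_at <- function(asthma, patients, pat_idx, week_start, rule) {
  out <- logical(length(pat_idx))
  birth <- patients$birth_date
  split_codes <- split(asthma$event_date, asthma$patient_id)
  for (id in names(split_codes)) {
    p <- match(id, patients$patient_id)
    sel <- which(pat_idx == p)
    if (!length(sel)) next
    codes <- sort(split_codes[[id]])
    ws <- week_start[sel]
    k <- findInterval(ws, codes)   # codes on the week start count as present
    has <- k > 0
    last_code <- codes[pmax(k, 1)]
    win <- ifelse(age_years(birth[p], ws) < 18,
                  rule$asthma_window_child_years,
                  rule$asthma_window_adult_years)
    out[sel] <- has & ws < add_years(last_code, win)
  }
  out
}

#' Eligible weeks for a single patient
#'
#' Convenience wrapper over [eligibility_table()] for one patient.
#'
#' @param patient One-row patient tibble.
#' @param events That patient's clinical events.
#' @inheritParams eligibility_table
#' @return Date vector of eligible week starts (possibly empty).
#' @export
eligible_weeks <- function(patient, events, rule, calendar, codelists = NULL) {
  stopifnot(nrow(patient) == 1)
  eligibility_table(patient, events, rule, calendar, codelists)$week_start
}

age_band_levels <- function() {
  paste(seq(11, 91, 10), seq(20, 100, 10), sep = "-")
}

age_band_at <- function(birth_date, at) {
  age <- pmin(pmax(age_years(birth_date, at), 11), 100)
  cut(age, breaks = c(seq(11, 91, 10), 101), labels = age_band_levels(),
      right = FALSE, include.lowest = TRUE)
}

#' Dynamic weekly denominators, overall and stratified
#'
#' Counts eligible persons per week for a condition's [cohort_rule()], as an
#' overall series and optionally stratified by age band (10-year bands 11-20
#' through 91-100, evaluated at the week start), sex, region or ethnicity.
#' Stratum counts partition the overall count exactly.
#'
#' @inheritParams eligibility_table
#' @param strata Character subset of
#'   `c("age_band", "sex", "region", "ethnicity")`.
#' @return A tibble `condition`, `stratifier`, `stratum`, `week_start`,
#'   `count` including a `stratifier = "overall"` series.
#' @export
build_denominators <- function(patients, events, rule, calendar,
                               strata = character(), codelists = NULL) {
  allowed <- c("age_band", "sex", "region", "ethnicity")
  bad <- setdiff(strata, allowed)
  if (length(bad)) {
    stop("unknown stratifier(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  elig <- eligibility_table(patients, events, rule, calendar, codelists)
  pidx <- match(elig$patient_id, patients$patient_id)

  tally <- function(stratum, levels) {
    df <- tibble::tibble(week_start = elig$week_start,
                         stratum = factor(stratum, levels = levels))
    counts <- dplyr::count(df, .data$week_start, .data$stratum,
                           .drop = FALSE, name = "count")
    full <- tidyr::expand_grid(week_start = calendar$week_start,
                               stratum = factor(levels, levels = levels))
    out <- dplyr::left_join(full, counts, by = c("week_start", "stratum"))
    out$count <- dplyr::coalesce(out$count, 0L)
    dplyr::mutate(out, stratum = as.character(.data$stratum))
  }

  res <- dplyr::bind_rows(c(
    list(overall = tally(rep("all", nrow(elig)), "all")),
    purrr::set_names(purrr::map(strata, function(s) {
      values <- switch(s,
        age_band = age_band_at(patients$birth_date[pidx], elig$week_start),
        factor(as.character(patients[[s]][pidx]),
               levels = levels(factor(patients[[s]])))
      )
      tally(values, levels(values))
    }), strata)
  ), .id = "stratifier")
  dplyr::bind_cols(tibble::tibble(condition = rule$condition,
                                  .rows = nrow(res)), res)
}
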