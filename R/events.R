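#' Define an outcome (event) rule
#'
#' An outcome definition turns coded records into clinical events: codes are
#' matched against a morbidity codelist, optionally required to co-occur
#' with a qualifying prescription (composite exacerbation algorithms), and
#' then collapsed so that multiple records within a condition-specific
#' window count as one event. Heart-failure-style outcomes instead count
#' only a person's first-ever diagnosis.
#'
#' @param condition Condition name.
#' @param morbidity_codelist Codelist name for diagnosis/symptom codes.
#' @param dedup_window_days Records within this many days of each other
#'   (chained, boundary inclusive) represent the same event. Ignored when
#'   `first_ever = TRUE`.
#' @param requires_prescription `"none"`, or the name(s) of prescription
#'   codelists one of which must co-occur (e.g. oral corticosteroid for
#'   asthma; corticosteroid or antibiotic for COPD).
#' @param co_occurrence_window_days A morbidity record qualifies iff a
#'   prescription exists within plus or minus this many days (default 0:
#'   same-day prescribing, the conservative reading of same-consultation
#'   algorithms).
#' @param new_rx_washout_days If positive, a prescription only qualifies
#'   when it is "new": no prescription from the same codelist in the
#'   preceding this-many days (used for COPD; 0 disables).
#' @param first_ever Count only the first-ever matched record; earlier
#'   records outside the study window still disqualify later ones.
#' @return An `outcome_definition` list.
#' @export
outcome_definition <- function(condition,
                               morbidity_codelist,
                               dedup_window_days = 7L,
                               requires_prescription = "none",
                               co_occurrence_window_days = 0L,
                               new_rx_washout_days = 0L,
                               first_ever = FALSE) {
  if (!first_ever && dedup_window_days <= 0) {
    stop("`dedup_window_days` must be positive unless first_ever", call. = FALSE)
  }
  structure(list(
    condition = condition,
    morbidity_codelist = morbidity_codelist,
    dedup_window_days = as.integer(dedup_window_days),
    requires_prescription = requires_prescription,
    co_occurrence_window_days = as.integer(co_occurrence_window_days),
    new_rx_washout_days = as.integer(new_rx_washout_days),
    first_ever = isTRUE(first_ever)
  ), class = "outcome_definition")
}

#' Match coded records against a codelist
#'
#' @param events Tibble with at least a `code` column.
#' @param codes Character vector of codes (or a codelist tibble, in which
#'   case all its codes are used).
#' @return The matching rows, order preserved.
#' @export
match_codes <- function(events, codes) {
  if (is.data.frame(codes)) codes <- codes$code
  events[events$code %in% codes, ]
}

#' Collapse dated records into episodes
#'
#' Greedy chain rule: a record starts a new episode iff its gap from the
#' immediately preceding record exceeds `window_days`; a gap exactly equal
#' to the window chains ("within N days of each other" is boundary
#' inclusive). Returns the first date of each episode, which stands for the
#' episode's onset.
#'
#' @param dates Sorted ascending Date vector.
#' @param window_days Positive integer window.
#' @return Date vector of episode start dates.
#' @export
#' @examples
#' dedup_episodes(as.Date("2020-01-01") + c(0, 3, 10), 7)
dedup_episodes <- function(dates, window_days) {
  dates <- as.Date(dates)
  if (length(dates) == 0) return(dates)
  if (is.unsorted(dates)) {
    stop("`dates` must be sorted ascending", call. = FALSE)
  }
  if (window_days <= 0) stop("`window_days` must be positive", call. = FALSE)
  starts <- c(TRUE, diff(as.numeric(dates)) > window_days)
  dates[starts]
}

#' First-ever event rule
#'
#' @param dates Sorted Date vector of a person's matched records.
#' @param study_start,study_end Study calendar bounds.
#' @return The earliest date if it falls inside the study window, else an
#'   empty Date vector; a first record before `study_start` disqualifies
#'   all later ones.
#' @export
first_ever_event <- function(dates, study_start, study_end) {
  dates <- as.Date(dates)
  if (length(dates) == 0) return(dates)
  if (is.unsorted(dates)) stop("`dates` must be sorted ascending", call. = FALSE)
  first <- dates[1]
  if (first >= as.Date(study_start) && first <= as.Date(study_end)) {
    first
  } else {
    dates[0]
  }
}

# Keep only "new" prescriptions: none from the same codelist in the
# preceding washout window (strictly before, chained per earlier kept rows
# is NOT applied -- newness is judged against any earlier prescription).
filter_new_prescriptions <- function(rx, washout_days) {
  if (washout_days <= 0 || nrow(rx) == 0) return(rx)
  rx <- dplyr::arrange(rx, .data$patient_id, .data$event_date)
  keep_by_patient <- purrr::map(
    split(as.numeric(rx$event_date), rx$patient_id),
    function(d) {
      vapply(seq_along(d), function(i) {
        gaps <- d[i] - d[seq_len(i - 1)]
        !any(gaps > 0 & gaps <= washout_days)
      }, logical(1))
    }
  )
  rx[unsplit(keep_by_patient, rx$patient_id), ]
}

#' Extract outcome events for one condition
#'
#' Applies an [outcome_definition()] to coded records: morbidity codelist
#' matching, optional prescription co-occurrence (with an optional
#' new-prescription washout), then per-patient deduplication with the
#' condition's window (or the first-ever rule). Deduplication chains run
#' over the full record, so an episode beginning before the study calendar
#' absorbs its in-study continuation records; only episodes starting inside
#' the calendar are emitted.
#'
#' @param clinical_events Tibble (`patient_id`, `event_date`, `code`).
#' @param prescriptions Tibble of prescription records, same columns.
#' @param definition An [outcome_definition()].
#' @param codelists Codelist tibble.
#' @param calendar A [week_grid()].
#' @return A tibble `condition`, `patient_id`, `event_date`, `week_start`.
#' @export
extract_events <- function(clinical_events, prescriptions, definition,
                           codelists, calendar) {
  stopifnot(inherits(definition, "outcome_definition"))
  morb <- match_codes(clinical_events,
                      codelist_codes(codelists, definition$morbidity_codelist))
  morb <- dplyr::arrange(morb, .data$patient_id, .data$event_date)

  if (!identical(definition$requires_prescription, "none")) {
    if (is.null(prescriptions)) {
      stop("condition '", definition$condition,
           "' requires prescriptions but none were supplied", call. = FALSE)
    }
    rx_codes <- unlist(purrr::map(definition$requires_prescription,
                                  codelist_codes, codelists = codelists))
    rx <- match_codes(prescriptions, rx_codes)
    rx <- filter_new_prescriptions(rx, definition$new_rx_washout_days)
    morb <- qualify_by_prescription(morb, rx,
                                    definition$co_occurrence_window_days)
  }

  study_start <- min(calendar$week_start)
  study_end <- max(calendar$week_start) + 6

  episodes <- purrr::map(split(morb$event_date, morb$patient_id), function(d) {
    d <- sort(unique(as.Date(d)))
    if (definition$first_ever) {
      first_ever_event(d, study_start, study_end)
    } else {
      dedup_episodes(d, definition$dedup_window_days)
    }
  })
  out <- tibble::tibble(
    patient_id = rep(names(episodes), lengths(episodes)),
    event_date = as.Date(unlist(episodes, use.names = FALSE),
                         origin = "1970-01-01")
  )
  out <- out[out$event_date >= study_start & out$event_date <= study_end, ]
  out <- dplyr::arrange(out, .data$patient_id, .data$event_date)
  tibble::tibble(
    condition = definition$condition,
    patient_id = out$patient_id,
    event_date = out$event_date,
    week_start = floor_week(out$event_date)
  )
}

# A morbidity record qualifies iff any prescription for the same patient
# falls within +/- window days of it.
qualify_by_prescription <- function(morb, rx, window_days) {
  if (nrow(morb) == 0) return(morb)
  rx_by_patient <- split(as.numeric(rx$event_date), rx$patient_id)
  d <- as.numeric(morb$event_date)
  ok <- vapply(seq_len(nrow(morb)), function(i) {
    rd <- rx_by_patient[[morb$patient_id[i]]]
    !is.null(rd) && any(abs(rd - d[i]) <= window_days)
  }, logical(1))
  morb[ok, ]
}
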