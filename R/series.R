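#' Build a weekly outcome series
#'
#' Joins outcome events to a weekly denominator series: the count for a week
#' is the number of distinct persons with an episode starting that week,
#' zero-filled over the full calendar, with `proportion = count /
#' denominator`. An event falling in a week with a zero denominator signals
#' a cohort/event mismatch and raises an error.
#'
#' @param events Outcome events (`patient_id`, `week_start`), e.g. from
#'   [extract_events()]. Persons are counted once per week.
#' @param denominators Either a tibble (`week_start`, `count`) for a single
#'   population series (e.g. one stratum of [build_denominators()]), or a
#'   (`week_start`, `denominator`) tibble.
#' @param calendar A [week_grid()].
#' @return A `WeeklySeries` tibble: `week_start`, `count`, `denominator`,
#'   `proportion`.
#' @export
weekly_series <- function(events, denominators, calendar) {
  denom_col <- if ("denominator" %in% names(denominators)) "denominator" else "count"
  if (any(c("stratifier", "stratum") %in% names(denominators))) {
    combos <- unique(denominators[intersect(c("stratifier", "stratum"),
                                            names(denominators))])
    if (nrow(combos) > 1) {
      stop("`denominators` holds several strata; filter to one first",
           call. = FALSE)
    }
  }
  idx <- match(calendar$week_start, denominators$week_start)
  if (anyNA(idx)) {
    stop("denominator series does not cover the calendar", call. = FALSE)
  }
  denom <- as.integer(denominators[[denom_col]][idx])

  wk <- dplyr::summarise(
    dplyr::group_by(events, .data$week_start),
    count = dplyr::n_distinct(.data$patient_id), .groups = "drop")
  count <- dplyr::coalesce(
    wk$count[match(calendar$week_start, wk$week_start)], 0L)

  bad <- count > 0 & denom == 0
  if (any(bad)) {
    stop("outcome events fall in week(s) with zero denominator (first: ",
         format(calendar$week_start[which(bad)[1]]),
         "); cohort and events disagree", call. = FALSE)
  }
  tibble::tibble(
    week_start = calendar$week_start,
    count = count,
    denominator = denom,
    proportion = ifelse(denom > 0, count / denom, NA_real_)
  )
}

#' Historical (pre-2020) weekly averages
#'
#' Aligns weeks by their ordinal index within the year on the study week
#' grid (1..53; years drift by weekday on a fixed Sunday grid, so ordinal
#' alignment is used rather than calendar dates) and summarises the pre-2020
#' proportions: mean, median and IQR across the available years. Weeks from
#' 2020 onwards never contribute.
#'
#' @param series A `WeeklySeries` tibble.
#' @param before First excluded year (default 2020).
#' @return A tibble `week_of_year`, `mean`, `median`, `q25`, `q75`, `n_years`.
#' @export
historical_average <- function(series, before = 2020) {
  yr <- lubridate::year(series$week_start)
  hist <- series[yr < before, ]
  if (nrow(hist) == 0) {
    stop("no pre-", before, " weeks available for a historical average",
         call. = FALSE)
  }
  hist_yr <- lubridate::year(hist$week_start)
  woy <- stats::ave(rep(1L, nrow(hist)), hist_yr, FUN = seq_along)
  dplyr::summarise(
    dplyr::group_by(tibble::tibble(week_of_year = as.integer(woy),
                                   proportion = hist$proportion),
                    .data$week_of_year),
    mean = mean(.data$proportion),
    median = stats::median(.data$proportion),
    q25 = stats::quantile(.data$proportion, 0.25, names = FALSE),
    q75 = stats::quantile(.data$proportion, 0.75, names = FALSE),
    n_years = dplyr::n(),
    .groups = "drop"
  )
}

#' Small-cell disclosure suppression
#'
#' Masks weekly counts strictly between zero and the threshold (default:
#' fewer than five contacts in a week), the usual disclosure-control rule
#' for published aggregate health data. Zeros are not disclosive and are
#' left untouched; masked counts become `NA` with `masked = TRUE`, so they
#' remain distinguishable from true zeros. Model fitting should use the
#' unsuppressed series; suppression is for published outputs.
#'
#' @param series A `WeeklySeries` tibble.
#' @param threshold Minimum publishable count (default 5).
#' @return The series with `count`/`proportion` masked and a `masked` flag.
#' @export
suppress_small_cells <- function(series, threshold = 5L) {
  if (threshold < 1) stop("`threshold` must be >= 1", call. = FALSE)
  masked <- series$count >= 1 & series$count < threshold
  series$masked <- masked
  series$count[masked] <- NA_integer_
  if ("proportion" %in% names(series)) series$proportion[masked] <- NA_real_
  series
}

#' Plot a weekly series against its historical average
#'
#' A plain rendering of the usual presentation: the 2020 percentage of the
#' population with contacts, overlaid on the 2017-19 weekly average.
#'
#' @param series A `WeeklySeries` tibble.
#' @param historical Optional output of [historical_average()].
#' @param year Focal year (default 2020).
#' @return A ggplot object.
#' @export
plot_weekly_series <- function(series, historical = NULL, year = 2020) {
  yr <- lubridate::year(series$week_start)
  focal <- series[yr == year, ]
  focal$week_of_year <- seq_len(nrow(focal))
  p <- ggplot2::ggplot(focal,
                       ggplot2::aes(x = .data$week_of_year,
                                    y = 100 * .data$proportion)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::labs(x = "Week of year", y = "% of population with contacts")
  if (!is.null(historical)) {
    p <- p + ggplot2::geom_line(
      data = historical,
      ggplot2::aes(x = .data$week_of_year, y = 100 * .data$mean),
      colour = "grey40", linetype = 2)
  }
  p
}
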