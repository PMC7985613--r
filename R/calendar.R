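#' Study week grid
#'
#' Weekly analyses in this package run on a fixed grid of consecutive 7-day
#' blocks anchored on Sunday January 1 2017. All of the key interruption
#' dates used by the default study design (March 8, March 29, April 26 and
#' June 28 2020) fall on Sundays of this grid, and the default study end
#' (July 18 2020) is the Saturday closing its final week.
#'
#' @param start First day of the first week. Must be on the Sunday grid.
#' @param end Last calendar day covered; the grid contains every week whose
#'   start is on or before `end`.
#' @return A tibble with one row per week: `week_start` (Date), `week_index`
#'   (1-based), `year`, `month` (integer 1-12 of the week start) and
#'   `week_of_year` (ordinal index of the week within its anchor year).
#' @export
#' @examples
#' week_grid()[1:3, ]
week_grid <- function(start = study_start(), end = study_end_date()) {
  start <- as.Date(start)
  end <- as.Date(end)
  if (is.na(start) || is.na(end) || end < start) {
    stop("`end` must be a date on or after `start`", call. = FALSE)
  }
  if (!is_on_week_grid(start)) {
    stop("`start` must fall on the Sunday week grid anchored at ",
         format(week_anchor()), call. = FALSE)
  }
  week_start <- seq(start, end, by = "7 days")
  yr <- lubridate::year(week_start)
  tibble::tibble(
    week_start = week_start,
    week_index = seq_along(week_start),
    year = as.integer(yr),
    month = as.integer(lubridate::month(week_start)),
    week_of_year = as.integer(stats::ave(rep(1L, length(yr)), yr, FUN = seq_along))
  )
}

#' @rdname week_grid
#' @export
week_anchor <- function() as.Date("2017-01-01")

#' @rdname week_grid
#' @export
study_start <- function() as.Date("2017-01-01")

#' @rdname week_grid
#' @export
study_end_date <- function() as.Date("2020-07-18")

is_on_week_grid <- function(date) {
  as.numeric(as.Date(date) - week_anchor()) %% 7 == 0
}

#' Snap dates to the start of their study week
#'
#' @param date Date vector.
#' @return The Sunday starting the grid week containing each date.
#' @export
floor_week <- function(date) {
  date <- as.Date(date)
  date - as.numeric(date - week_anchor()) %% 7
}

as_date_scalar <- function(x, what) {
  out <- tryCatch(as.Date(x), error = function(e) NA)
  if (length(out) != 1 || is.na(out)) {
    stop("`", what, "` must be a single interpretable date", call. = FALSE)
  }
  out
}
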