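#' Fit the Poisson counterpart of the ITS model
#'
#' A log-link count model with a log-denominator offset and the same
#' covariates (trend, step, recovery interaction, month dummies, lagged
#' residuals) as [fit_its()], with quasi-likelihood dispersion scaling of
#' the standard errors. Used to translate the relative step and recovery
#' into absolute expected contact counts.
#'
#' @inheritParams fit_its
#' @return An `its_poisson_fit` object (also an `its_fit`).
#' @export
fit_poisson_its <- function(series, design = its_design(), condition = NULL) {
  fit_its_engine(series, design, stats::poisson(), condition)
}

#' Counterfactual weekly contact deficits per million
#'
#' Compares model-expected weekly contacts per million persons with
#' restrictions (the fitted trajectory) against the no-restrictions
#' counterfactual in which the whole restriction effect -- the step and the
#' recovery interaction -- is set to zero. Both trajectories evaluate the
#' lagged-residual term at its process mean of zero. Differences are
#' counterfactual minus observed-model (positive = contacts lost), with a
#' running cumulative sum from `restriction_start`.
#'
#' @param fit An [fit_poisson_its()] object.
#' @param window Optional length-2 Date vector restricting the output weeks;
#'   must lie within the with-restrictions period.
#' @return A `CounterfactualEstimate` tibble: `week_start`,
#'   `expected_without`, `expected_with`, `difference`, `cumulative`
#'   (all per million persons).
#' @export
counterfactual_difference <- function(fit, window = NULL) {
  if (!inherits(fit, "its_poisson_fit")) {
    stop("`fit` must come from fit_poisson_its()", call. = FALSE)
  }
  df <- fit$data[fit$data$restriction == 1, ]
  nd_with <- df
  nd_with$denominator <- 1e6
  if ("lag_resid" %in% names(df)) nd_with$lag_resid <- 0
  nd_without <- nd_with
  nd_without$restriction <- 0
  nd_without$weeks_since <- 0

  with_rate <- as.numeric(stats::predict(fit$model, newdata = nd_with,
                                         type = "response"))
  without_rate <- as.numeric(stats::predict(fit$model, newdata = nd_without,
                                            type = "response"))
  out <- tibble::tibble(
    week_start = df$week_start,
    expected_without = without_rate,
    expected_with = with_rate,
    difference = without_rate - with_rate,
    cumulative = cumsum(without_rate - with_rate)
  )
  if (!is.null(window)) {
    window <- as.Date(window)
    if (window[1] < fit$design$restriction_start) {
      stop("`window` must lie within the with-restrictions period",
           call. = FALSE)
    }
    out <- out[out$week_start >= window[1] & out$week_start <= window[2], ]
  }
  out
}

#' Presentation rounding and censoring of absolute effects
#'
#' Rounds to 3 significant figures (avoiding overly precise estimates) and
#' censors small magnitudes below a disclosure/precision threshold: a
#' positive deficit under the threshold prints as `"<threshold"`, a
#' negative one (an excess of contacts) as `">-threshold"`. Thousands are
#' grouped with a space.
#'
#' @param value Numeric values (contacts per million).
#' @param threshold Censoring threshold, typically 10 for rare conditions
#'   and 100 otherwise.
#' @return Character presentation strings.
#' @export
#' @examples
#' round_and_censor(c(43912, 7, -45, 330), threshold = c(100, 10, 100, 100))
round_and_censor <- function(value, threshold = 100) {
  n <- max(length(value), length(threshold))
  value <- rep_len(value, n)
  threshold <- rep_len(threshold, n)
  vapply(seq_len(n), function(i) {
    v <- value[i]
    thr <- threshold[i]
    if (is.na(v)) return(NA_character_)
    if (abs(v) < thr) {
      if (v >= 0) paste0("<", format(thr, big.mark = " ", scientific = FALSE))
      else paste0(">-", format(thr, big.mark = " ", scientific = FALSE))
    } else {
      format(signif(v, 3), big.mark = " ", scientific = FALSE)
    }
  }, character(1))
}

#' Snapshot table of absolute effects
#'
#' Summarises a counterfactual trajectory at snapshot weeks (defaults: the
#' weeks beginning April 26 and June 28 2020, i.e. 1 month and 3 months into
#' the with-restrictions period): expected weekly contacts per million with
#' and without restrictions, the weekly difference, and the cumulative
#' deficit since the restriction start, with presentation strings under the
#' 3-significant-figure rounding and censoring rules.
#'
#' @param cf Output of [counterfactual_difference()].
#' @param snapshot_weeks Dates (week starts) to report.
#' @param threshold Censoring threshold for this condition (10 or 100).
#' @param condition Optional condition label.
#' @return A tibble with one row per snapshot week.
#' @export
snapshot_table <- function(cf,
                           snapshot_weeks = as.Date(c("2020-04-26",
                                                      "2020-06-28")),
                           threshold = 100,
                           condition = NULL) {
  rows <- cf[cf$week_start %in% as.Date(snapshot_weeks), ]
  if (nrow(rows) == 0) {
    stop("no counterfactual rows at the requested snapshot weeks",
         call. = FALSE)
  }
  tibble::tibble(
    condition = condition %||% NA_character_,
    week_start = rows$week_start,
    expected_without = round(rows$expected_without),
    expected_with = round(rows$expected_with),
    weekly_difference = round_and_censor(rows$difference, threshold),
    cumulative_difference = round_and_censor(rows$cumulative, threshold)
  )
}
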