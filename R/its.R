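#' Define an interrupted time-series design
#'
#' The design splits the weekly calendar into a pre-interruption segment, an
#' excluded adjustment window (behaviour was already changing before
#' restrictions were announced, so those weeks carry no information about
#' either segment), and a with-restrictions segment. Defaults follow the
#' usual 2020 analysis: pre-period Jan 1 2017 to March 7 2020, exclusion
#' March 8-28 2020, restrictions March 29 to July 18 2020.
#'
#' @param pre_period_start First calendar day of the pre-period (some
#'   outcomes, e.g. self-harm, use a shortened pre-period from Jan 1 2019).
#' @param pre_period_end Last day of the pre-period.
#' @param exclusion_start,exclusion_end Excluded adjustment window; use
#'   `NULL` for designs with no excluded weeks.
#' @param restriction_start First day of the with-restrictions period (a
#'   Sunday on the week grid).
#' @param study_end Last day of follow-up.
#' @param include_trend Include the linear weekly trend term.
#' @param include_month_dummies Include calendar month as a categorical
#'   covariate (January reference).
#' @param include_lagged_residuals Adjust for autocorrelation by refitting
#'   with the first-order lagged residual of a first-stage fit.
#' @param lag_residual_type Residual type for the lag term
#'   (`"deviance"`, `"pearson"` or `"response"`).
#' @return An `its_design` list.
#' @export
its_design <- function(pre_period_start = as.Date("2017-01-01"),
                       pre_period_end = as.Date("2020-03-07"),
                       exclusion_start = as.Date("2020-03-08"),
                       exclusion_end = as.Date("2020-03-28"),
                       restriction_start = as.Date("2020-03-29"),
                       study_end = as.Date("2020-07-18"),
                       include_trend = TRUE,
                       include_month_dummies = TRUE,
                       include_lagged_residuals = TRUE,
                       lag_residual_type = c("deviance", "pearson", "response")) {
  d <- list(
    pre_period_start = as_date_scalar(pre_period_start, "pre_period_start"),
    pre_period_end = as_date_scalar(pre_period_end, "pre_period_end"),
    exclusion_start = if (!is.null(exclusion_start))
      as_date_scalar(exclusion_start, "exclusion_start"),
    exclusion_end = if (!is.null(exclusion_end))
      as_date_scalar(exclusion_end, "exclusion_end"),
    restriction_start = as_date_scalar(restriction_start, "restriction_start"),
    study_end = as_date_scalar(study_end, "study_end"),
    include_trend = isTRUE(include_trend),
    include_month_dummies = isTRUE(include_month_dummies),
    include_lagged_residuals = isTRUE(include_lagged_residuals),
    lag_residual_type = match.arg(lag_residual_type)
  )
  if (!(d$pre_period_start < d$pre_period_end &&
        d$pre_period_end < d$restriction_start &&
        d$restriction_start <= d$study_end)) {
    stop("need pre_period_start < pre_period_end < restriction_start <= ",
         "study_end", call. = FALSE)
  }
  if (xor(is.null(d$exclusion_start), is.null(d$exclusion_end))) {
    stop("supply both or neither of exclusion_start/exclusion_end",
         call. = FALSE)
  }
  if (!is.null(d$exclusion_start) &&
      !(d$pre_period_end < d$exclusion_start &&
        d$exclusion_start <= d$exclusion_end &&
        d$exclusion_end < d$restriction_start)) {
    stop("the exclusion window must lie strictly between pre_period_end and ",
         "restriction_start", call. = FALSE)
  }
  structure(d, class = "its_design")
}

#' Build the ITS model frame
#'
#' One row per retained week: the pre-period weeks (weeks ending by
#' `pre_period_end`, starting no earlier than `pre_period_start`) and the
#' with-restrictions weeks. Covariates: `t`, the week index centred at the
#' last pre-period week (so the step coefficient contrasts the start of the
#' with-restrictions period against the end of the pre-period trend);
#' `restriction`, the 0/1 segment indicator; `weeks_since`, the
#' restriction-by-time interaction (0 at `restriction_start`, incrementing
#' weekly); and `month`, the calendar month of the week start with January
#' as reference.
#'
#' @param series A `WeeklySeries` tibble (`week_start`, `count`,
#'   `denominator`).
#' @param design An [its_design()].
#' @return The model-ready tibble.
#' @export
build_design_matrix <- function(series, design) {
  stopifnot(inherits(design, "its_design"))
  ws <- as.Date(series$week_start)
  pre <- ws >= design$pre_period_start & (ws + 6) <= design$pre_period_end
  post <- ws >= design$restriction_start & ws <= design$study_end
  keep <- (pre | post)
  if (!any(post)) {
    stop("no with-restrictions weeks in the series for this design",
         call. = FALSE)
  }
  if (!any(pre)) {
    stop("no pre-period weeks in the series for this design", call. = FALSE)
  }
  df <- series[keep, ]
  ws <- as.Date(df$week_start)
  last_pre <- max(ws[ws + 6 <= design$pre_period_end])
  restriction <- as.integer(ws >= design$restriction_start)
  tibble::tibble(
    week_start = ws,
    count = df$count,
    denominator = df$denominator,
    t = as.numeric(ws - last_pre) / 7,
    restriction = restriction,
    weeks_since = restriction * as.numeric(ws - design$restriction_start) / 7,
    month = factor(month.abb[lubridate::month(ws)], levels = month.abb)
  )
}

its_formula <- function(design, lagged = FALSE, poisson = FALSE) {
  lhs <- if (poisson) "count" else "cbind(count, denominator - count)"
  rhs <- c(if (design$include_trend) "t",
           "restriction", "weeks_since",
           if (design$include_month_dummies) "month",
           if (lagged) "lag_resid",
           if (poisson) "offset(log(denominator))")
  stats::as.formula(paste(lhs, "~", paste(rhs, collapse = " + ")))
}

fit_its_engine <- function(series, design, family, condition = NULL) {
  df <- build_design_matrix(series, design)
  if (any(df$denominator <= 0)) {
    stop("retained weeks must all have positive denominators",
         " (condition: ", condition %||% "unknown", ")", call. = FALSE)
  }
  poisson <- identical(family$family, "poisson")
  df$month <- droplevels(df$month)

  fit_stage <- function(formula, data) {
    fit <- tryCatch(
      withCallingHandlers(
        stats::glm(formula, family = family, data = data,
                   control = stats::glm.control(maxit = 100)),
        warning = function(w) {
          # an exactly-fitting series leaves IRLS polishing numerical noise;
          # the deviance check below decides whether convergence truly failed
          if (grepl("did not converge", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        }
      ),
      error = function(e) stop("ITS fit failed for condition '",
                               condition %||% "unknown", "': ",
                               conditionMessage(e), call. = FALSE)
    )
    if (!fit$converged && stats::deviance(fit) > 1e-6) {
      stop("ITS fit did not converge for condition '",
           condition %||% "unknown", "'", call. = FALSE)
    }
    fit
  }

  stage1 <- fit_stage(its_formula(design, lagged = FALSE, poisson = poisson), df)
  model <- stage1
  if (design$include_lagged_residuals) {
    r <- stats::residuals(stage1, type = design$lag_residual_type)
    # retained rows are in time order; the lag bridges the exclusion gap,
    # and the first retained row has no predecessor so its lag is 0
    df$lag_resid <- c(0, r[-length(r)])
    if (stats::sd(df$lag_resid) > 0) {
      model <- fit_stage(its_formula(design, lagged = TRUE, poisson = poisson), df)
    } else {
      df$lag_resid <- NULL
    }
  }

  phi <- sum(stats::residuals(model, type = "pearson")^2) /
    stats::df.residual(model)
  scale <- max(phi, 1)  # never deflate below the nominal model
  vc <- stats::vcov(model) * scale

  structure(list(
    model = model,
    stage1 = stage1,
    data = df,
    design = design,
    family = family$family,
    dispersion = phi,
    vcov_scaled = vc,
    condition = condition
  ), class = c(if (poisson) "its_poisson_fit", "its_fit"))
}

#' Fit the interrupted time-series binomial model
#'
#' Two-stage quasi-binomial fit of weekly contact proportions: (1) a
#' binomial GLM (logit link) of `cbind(count, denominator - count)` on the
#' [build_design_matrix()] covariates, which weights each week by its
#' dynamic denominator; (2) if the design requests it, a refit adding the
#' first-order lagged residual of stage 1 to absorb autocorrelation. The
#' dispersion \eqn{\phi} is the Pearson chi-square over residual degrees of
#' freedom of the final fit; standard errors are scaled by
#' \eqn{\sqrt{\phi}} when \eqn{\phi > 1} (never deflated).
#'
#' @param series A `WeeklySeries` tibble.
#' @param design An [its_design()].
#' @param condition Optional condition label carried into errors and output.
#' @return An `its_fit` object; see [step_or()], [recovery_or()],
#'   [generics::tidy()], [generics::glance()].
#' @export
fit_its <- function(series, design = its_design(), condition = NULL) {
  fit_its_engine(series, design, stats::binomial(), condition)
}

scaled_coef <- function(fit, term) {
  co <- stats::coef(fit$model)
  if (!term %in% names(co) || is.na(co[[term]])) {
    return(list(est = NA_real_, se = NA_real_))
  }
  list(est = unname(co[[term]]),
       se = sqrt(fit$vcov_scaled[term, term]))
}

or_row <- function(term, est, se, z = stats::qnorm(0.975)) {
  tibble::tibble(
    term = term,
    log_or = est,
    se = se,
    estimate = exp(est),
    conf.low = exp(est - z * se),
    conf.high = exp(est + z * se)
  )
}

#' Step odds ratio
#'
#' The immediate multiplicative change in weekly odds of contact at the
#' start of the with-restrictions period relative to the end of the
#' pre-period trend: `exp` of the restriction-step coefficient, with a Wald
#' 95% CI on overdispersion-scaled standard errors.
#'
#' @param fit An [fit_its()] object.
#' @return A one-row tibble: `term`, `log_or`, `se`, `estimate`,
#'   `conf.low`, `conf.high`.
#' @export
step_or <- function(fit) {
  s <- scaled_coef(fit, "restriction")
  or_row("step", s$est, s$se)
}

#' Recovery (weekly slope) odds ratios
#'
#' Two summaries of the with-restrictions recovery: `slope_change`, the
#' interaction coefficient `exp(delta)` (change in weekly trend relative to
#' the pre-period trend), and `net_weekly`, `exp(beta1 + delta)`, the net
#' weekly multiplicative change in odds during the with-restrictions period
#' (the headline recovery measure reported by this package), with a
#' delta-method CI for the sum from the scaled covariance.
#'
#' @param fit An [fit_its()] object.
#' @return A two-row tibble as in [step_or()].
#' @export
recovery_or <- function(fit) {
  dl <- scaled_coef(fit, "weeks_since")
  slope <- or_row("slope_change", dl$est, dl$se)
  if (fit$design$include_trend) {
    co <- stats::coef(fit$model)
    est <- unname(co[["t"]] + co[["weeks_since"]])
    v <- fit$vcov_scaled
    se <- sqrt(v["t", "t"] + v["weeks_since", "weeks_since"] +
                 2 * v["t", "weeks_since"])
  } else {
    est <- dl$est
    se <- dl$se
  }
  dplyr::bind_rows(slope, or_row("net_weekly", est, se))
}

#' @export
print.its_fit <- function(x, ...) {
  kind <- if (inherits(x, "its_poisson_fit")) "Poisson count" else "binomial proportion"
  cat("Interrupted time-series fit (", kind, ")\n", sep = "")
  if (!is.null(x$condition)) cat("Condition:", x$condition, "\n")
  cat("Weeks used:", nrow(x$data),
      "| dispersion phi =", format(x$dispersion, digits = 4), "\n")
  s <- step_or(x)
  r <- recovery_or(x)
  cat(sprintf("Step %s: %.3f (95%% CI %.3f-%.3f)\n",
              if (inherits(x, "its_poisson_fit")) "rate ratio" else "OR",
              s$estimate, s$conf.low, s$conf.high))
  cat(sprintf("Net weekly recovery: %.4f (95%% CI %.4f-%.4f)\n",
              r$estimate[2], r$conf.low[2], r$conf.high[2]))
  invisible(x)
}

#' Tidy an ITS fit
#'
#' Coefficient table with overdispersion-scaled standard errors and Wald
#' statistics, in the usual broom layout.
#'
#' @param x An `its_fit`.
#' @param exponentiate Report `exp(estimate)` and exponentiated CI bounds.
#' @param ... Unused.
#' @return A tibble with one row per model term.
#' @export
tidy.its_fit <- function(x, exponentiate = FALSE, ...) {
  co <- stats::coef(x$model)
  co <- co[!is.na(co)]
  se <- sqrt(diag(x$vcov_scaled))[names(co)]
  z <- stats::qnorm(0.975)
  out <- tibble::tibble(
    term = names(co),
    estimate = unname(co),
    std.error = unname(se),
    statistic = unname(co / se),
    p.value = 2 * stats::pnorm(-abs(unname(co / se))),
    conf.low = unname(co - z * se),
    conf.high = unname(co + z * se)
  )
  if (exponentiate) {
    out$estimate <- exp(out$estimate)
    out$conf.low <- exp(out$conf.low)
    out$conf.high <- exp(out$conf.high)
  }
  out
}

#' Glance at an ITS fit
#'
#' @param x An `its_fit`.
#' @param ... Unused.
#' @return A one-row tibble of fit summaries.
#' @export
glance.its_fit <- function(x, ...) {
  tibble::tibble(
    n_weeks = nrow(x$data),
    n_pre = sum(x$data$restriction == 0),
    n_post = sum(x$data$restriction == 1),
    dispersion = x$dispersion,
    lag_coefficient = if ("lag_resid" %in% names(stats::coef(x$model)))
      unname(stats::coef(x$model)[["lag_resid"]]) else NA_real_,
    deviance = stats::deviance(x$model),
    df.residual = stats::df.residual(x$model)
  )
}

#' Fitted weekly proportions from an ITS fit
#'
#' @param fit An `its_fit`.
#' @return The model frame with a `fitted` column (proportion scale for the
#'   binomial model, expected count for the Poisson model).
#' @export
fitted_series <- function(fit) {
  df <- fit$data
  df$fitted <- unname(stats::fitted(fit$model))
  df
}

#' Plot an ITS fit
#'
#' Observed weekly percentages with the fitted model curve, the excluded
#' adjustment window shaded.
#'
#' @param object An `its_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.its_fit <- function(object, ...) {
  df <- fitted_series(object)
  if (inherits(object, "its_poisson_fit")) {
    df$obs <- df$count / df$denominator
    df$fit_prop <- df$fitted / df$denominator
  } else {
    df$obs <- df$count / df$denominator
    df$fit_prop <- df$fitted
  }
  des <- object$design
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$week_start)) +
    ggplot2::geom_point(ggplot2::aes(y = 100 * .data$obs),
                        size = 0.6, colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = 100 * .data$fit_prop,
                                    group = .data$restriction),
                       colour = "firebrick") +
    ggplot2::labs(x = NULL, y = "% of population with contacts",
                  title = object$condition)
  if (!is.null(des$exclusion_start)) {
    p <- p + ggplot2::annotate("rect",
                               xmin = des$exclusion_start,
                               xmax = des$exclusion_end,
                               ymin = -Inf, ymax = Inf,
                               alpha = 0.15, fill = "steelblue")
  }
  p
}
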