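bare_design <- its_design(include_trend = FALSE,
                          include_month_dummies = FALSE,
                          include_lagged_residuals = FALSE)

test_that("design validation enforces the period ordering", {
  expect_error(its_design(pre_period_end = as.Date("2020-04-01")),
               "pre_period_end < restriction_start|exclusion window")
  expect_error(its_design(restriction_start = as.Date("2020-03-20")),
               "exclusion window|pre_period_end")
  expect_error(its_design(exclusion_start = NULL), "both or neither")
  # a no-exclusion design is legitimate
  d0 <- its_design(pre_period_end = as.Date("2020-03-21"),
                   exclusion_start = NULL, exclusion_end = NULL,
                   restriction_start = as.Date("2020-03-22"))
  expect_s3_class(d0, "its_design")
})

test_that("the design matrix retains and codes exactly the right weeks", {
  series <- two_level_series()
  df <- build_design_matrix(series, its_design())
  dropped <- setdiff(series$week_start, df$week_start)
  expect_equal(sort(as.Date(dropped, origin = "1970-01-01")),
               as.Date(c("2020-03-08", "2020-03-15", "2020-03-22")))
  expect_equal(nrow(df), 182)
  expect_equal(unique(df$restriction[df$week_start < as.Date("2020-03-29")]), 0L)
  expect_equal(unique(df$restriction[df$week_start >= as.Date("2020-03-29")]), 1L)
  # interaction: 0 through the pre-period, then 0,1,2,... weekly
  expect_true(all(df$weeks_since[df$restriction == 0] == 0))
  expect_equal(df$weeks_since[df$restriction == 1], 0:15)
  # time index centred on the last pre-lockdown week
  expect_equal(df$t[df$week_start == as.Date("2020-03-01")], 0)
  expect_equal(levels(df$month)[1], "Jan")
  expect_error(build_design_matrix(series[series$week_start <
                                            as.Date("2020-03-29"), ],
                                   its_design()), "with-restrictions")
})

test_that("a flat series yields a unit step odds ratio", {
  s <- two_level_series(p_pre = 0.02, p_post = 0.02)
  fit <- fit_its(s, its_design())
  expect_lt(abs(step_or(fit)$estimate - 1), 1e-6)
})

test_that("a pure two-level series recovers the closed-form odds ratio", {
  s <- two_level_series(p_pre = 0.02, p_post = 0.01)
  fit <- fit_its(s, bare_design)
  truth <- (0.01 / 0.99) / (0.02 / 0.98)
  expect_lt(abs(step_or(fit)$estimate - truth), 1e-4)
})

test_that("odds-ratio intervals are the exponentiated Wald forms", {
  row <- careits:::or_row("step", log(0.5), 0.1)
  expect_equal(row$estimate, 0.5)
  expect_equal(row$conf.low, exp(log(0.5) - qnorm(0.975) * 0.1),
               tolerance = 1e-12)
  expect_equal(round(row$conf.low, 3), 0.411)
  expect_equal(round(row$conf.high, 3), 0.608)

  s <- two_level_series(0.02, 0.015)
  fit <- fit_its(s, its_design())
  so <- step_or(fit)
  expect_true(so$conf.low <= so$estimate & so$estimate <= so$conf.high)
  expect_gt(so$conf.low, 0)
})

test_that("recovery summaries combine trend and interaction correctly", {
  # no slope anywhere: both recovery ORs are 1
  s <- two_level_series(0.02, 0.02)
  r <- recovery_or(fit_its(s, its_design()))
  expect_equal(r$term, c("slope_change", "net_weekly"))
  expect_lt(max(abs(r$estimate - 1)), 1e-6)

  # pure post-restriction slope, no pre-trend: net weekly OR = exp(delta)
  cal <- week_grid()
  post_w <- pmax(0, as.numeric(cal$week_start - as.Date("2020-03-29")) / 7)
  eta <- qlogis(0.02) + ifelse(cal$week_start >= as.Date("2020-03-29"),
                               log(1.02) * post_w, 0)
  s2 <- tibble::tibble(week_start = cal$week_start,
                       count = as.integer(round(1e6 * plogis(eta))),
                       denominator = 1e6L)
  r2 <- recovery_or(fit_its(s2, its_design(include_month_dummies = FALSE,
                                           include_lagged_residuals = FALSE)))
  expect_equal(r2$estimate[r2$term == "net_weekly"], 1.02, tolerance = 1e-3)
})

test_that("step and recovery estimates recover generating values", {
  step_true <- log(0.35)
  slope_true <- log(1.03)
  ests <- t(vapply(1:20, function(seed) {
    cfg <- sim_config(baseline_logit = qlogis(0.002), step_log_or = step_true,
                      slope_log_or_per_week = slope_true,
                      month_effects = seasonal_month_effects(0.1),
                      ar_rho = 0.3, ar_sigma = 0.05, seed = seed)
    fit <- fit_its(simulate_weekly_counts(cfg))
    c(step = step_or(fit)$log_or,
      net = recovery_or(fit)$log_or[2])
  }, numeric(2)))
  expect_lt(abs(mean(ests[, "step"]) - step_true),
            2 * sd(ests[, "step"]) / sqrt(20))
  expect_lt(abs(mean(ests[, "net"]) - slope_true),
            2 * sd(ests[, "net"]) / sqrt(20))
})

test_that("the step log-OR is nearly unbiased at scale", {
  # depression-scale baseline, denominator 1e6
  ests <- vapply(1:200, function(seed) {
    cfg <- sim_config(baseline_logit = qlogis(0.0025),
                      step_log_or = log(0.53),
                      month_effects = seasonal_month_effects(0.1),
                      ar_rho = 0.3, ar_sigma = 0.05, seed = seed)
    step_or(fit_its(simulate_weekly_counts(cfg)))$log_or
  }, numeric(1))
  expect_lt(abs(mean(ests) - log(0.53)), 0.01)
})

test_that("scaling counts and denominators by 10 leaves the step OR fixed", {
  cfg <- null_sim_config(seed = 5, ar_rho = 0.3)
  s <- simulate_weekly_counts(cfg)[c("week_start", "count", "denominator")]
  s10 <- dplyr::mutate(s, count = count * 10L, denominator = denominator * 10L)
  expect_equal(step_or(fit_its(s, its_design()))$log_or,
               step_or(fit_its(s10, its_design()))$log_or, tolerance = 1e-10)
})

test_that("the lagged-residual stage removes residual autocorrelation", {
  ac1 <- function(r) stats::cor(r[-1], r[-length(r)])
  delta <- vapply(1:100, function(seed) {
    cfg <- null_sim_config(seed, ar_rho = 0.3)
    fit <- fit_its(simulate_weekly_counts(cfg))
    abs(ac1(stats::residuals(fit$stage1, "deviance"))) -
      abs(ac1(stats::residuals(fit$model, "deviance")))
  }, numeric(1))
  expect_gt(stats::median(delta), 0)
})

test_that("fits report the dispersion and expose tidy/glance/plot methods", {
  cfg <- null_sim_config(seed = 9)
  fit <- fit_its(simulate_weekly_counts(cfg), condition = "depression")
  expect_gt(fit$dispersion, 1)  # sigma = 0.05 forces overdispersion
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std.error") %in% names(td)))
  expect_true("restriction" %in% td$term)
  # scaled SEs are never below the unscaled binomial SEs
  unscaled <- sqrt(diag(stats::vcov(fit$model)))[td$term]
  expect_true(all(td$std.error >= unscaled - 1e-12))
  g <- glance(fit)
  expect_equal(g$n_weeks, 182)
  expect_equal(g$n_post, 16)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_output(print(fit), "Step OR")
})

test_that("errors carry the condition name and guard the denominators", {
  s <- two_level_series()
  s$denominator[5] <- 0L
  expect_error(fit_its(s, its_design(), condition = "depression"),
               "depression")
})
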