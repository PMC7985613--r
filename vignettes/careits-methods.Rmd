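---
title: "Methods: segmented regression of weekly primary-care contact series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmented regression of weekly primary-care contact series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(careits)
```

This vignette documents the models, the synthetic data-generating process,
the numerical choices, and the design decisions behind `careits`, in the
spirit of a model-methods appendix. Nothing stated here is an empirical
claim beyond what the package's tests and `scripts/acceptance.R` compute.

## Study layout

All weekly quantities live on a fixed grid of 7-day blocks anchored on
Sunday January 1 2017 (`week_grid()`). The default design (`its_design()`)
splits the grid into:

* a **pre-interruption period**, January 1 2017 – March 7 2020 (166 weeks);
* an excluded **adjustment window**, March 8–28 2020 (3 weeks): population
  behaviour was already shifting before restrictions were formally
  announced, so these weeks inform neither segment;
* a **with-restrictions period**, March 29 – July 18 2020 (16 weeks).

All the boundary dates are Sundays on the grid (July 18 2020 is the
Saturday closing the final week), which is why the grid is anchored where
it is. Sensitivity analysis (`default_sensitivity_grid()`) varies the
pre-period end (March 7 vs March 21) and the exclusion length (0–7 weeks)
over seven standard scenarios.

Outcomes with sparse histories can shorten the pre-period; the built-in
configuration does this for self-harm (from January 1 2019), mirroring the
usual practice of dropping early years whose recording differs.

## The binomial ITS model

For week $t$ with $c_t$ distinct persons contacting out of an eligible
denominator $n_t$ (updated weekly), the package fits

$$\operatorname{logit} p_t = \alpha + \beta_1 t + \gamma R_t +
\delta R_t (t - t_0) + s_{m(t)} + \rho\, r_{t-1}$$

by binomial GLM with `cbind(count, denominator - count)` as response —
i.e. weekly contacts weighted by the dynamic population sizes. $R_t$
indicates the with-restrictions period; $t$ counts weeks and is centred at
the last pre-interruption week so that $\gamma$ contrasts the start of the
with-restrictions period against the end of the pre-period trend; the
interaction is zero at the first restricted week and increments weekly;
$s_{m(t)}$ are calendar-month offsets (January reference). Fitting is
two-stage: the model is first fitted without $r_{t-1}$, then refitted with
the lag-1 residual (deviance scale by default; Pearson/response are
options) appended as a covariate. Retained rows are in time order and the
lag bridges the exclusion gap — the first with-restrictions row lags the
last pre-period row — with the first row's lag set to 0.

Overdispersion $\varphi$ is the Pearson $\chi^2$ over residual degrees of
freedom of the final fit; the covariance is scaled by $\max(\varphi, 1)$
(never deflated below the nominal binomial model). Intervals are Wald with
the normal 0.975 quantile. Reported summaries:

* `step_or()`: $e^{\gamma}$ with scaled-SE CI;
* `recovery_or()`: both $e^{\delta}$ (slope change) and the headline
  $e^{\beta_1 + \delta}$ (net weekly trend under restrictions), the latter
  with a delta-method CI from the scaled covariance. Reporting
  $e^{\beta_1+\delta}$ as the headline is this package's choice; both are
  always returned because published analyses are often ambiguous between
  the two (they coincide when the pre-trend is flat).

Degenerate inputs are handled explicitly: an exactly-fitting series leaves
IRLS polishing numerical noise below its convergence tolerance, so a fit
with deviance below $10^{-6}$ is accepted as converged; an all-zero lag
column (possible only for perfect fits) is dropped rather than producing a
rank-deficient refit; zero denominators and empty segments raise errors
naming the condition.

## Absolute effects

`fit_poisson_its()` refits the same design as a log-link count model with
`offset(log(denominator))` (an offset rather than pre-scaled rates: it
keeps the likelihood on the observed counts and makes the per-million
scaling explicit at prediction time). `counterfactual_difference()`
predicts each with-restrictions week twice with the denominator set to one
million: once as fitted and once with the *whole* restriction effect —
step and interaction — zeroed. A counterfactual of "no restrictions"
leaves no channel for either term, which is why both are zeroed rather
than the step alone. The lagged-residual term is evaluated at its process
mean of zero in both arms, so the comparison is between deterministic
trajectories rather than one noise path and one smooth curve. Weekly
differences (counterfactual minus fitted; positive = contacts lost)
accumulate from the restriction start.

For presentation, `round_and_censor()` rounds to 3 significant figures
(thousands grouped with a space) and censors magnitudes below a
per-condition threshold as `"<10"`/`"<100"`, with excesses (negative
differences) as `">-10"`/`">-100"`. Thresholds are configuration, not
inference: 10 for rare conditions, 100 otherwise, in
`default_condition_scenarios()`.

## Cohorts and events

Eligibility is evaluated at the week start — one consistent instant; a
patient dying mid-week still counts for that week's denominator. The rules
(`cohort_rule()`):

* age in completed years against a birth date materialised as July 1 of
  the birth year (year-resolution birth dates mirror de-identified EHR
  precision; the July-1 convention makes age arithmetic deterministic);
* a 1-year registration run-in;
* chronic-disease entry from the first dated diagnosis code (diabetes,
  COPD); smoking history (COPD) means any smoking code strictly before the
  week under evaluation;
* asthma currency: the most recent asthma code must be strictly within 2
  years (under 18) or 3 years (18+) of the week start — a week is eligible
  iff `week_start < code_date + window` — and eligibility can lapse and
  re-enter on a later code. The strict boundary is a documented choice;
  the source rules do not state whether the boundary week is inclusive;
* asthma-to-COPD reclassification: an asthma record in a patient aged 40+
  is discounted if any COPD code follows within 2 years. Because the rule
  looks forward, eligibility is computed retrospectively over the full
  record.

Event extraction (`extract_events()`) matches morbidity codelists, then
(for exacerbations) requires a qualifying prescription within a
co-occurrence window (default 0 days — same-day prescribing, the
conservative reading of same-consultation algorithms; configurable because
the validated algorithms are ambiguous between same-day and wider
windows). A "new" prescription (COPD) is one with no same-class
prescription in the preceding 28 days (configurable; distinguishes acute
courses from repeats). Qualifying records deduplicate per patient by a
greedy chain: a record starts a new episode iff its gap from the
immediately preceding record exceeds the window, boundary inclusive
("within N days of each other" chains at exactly N). The chain runs over
the full record, so an episode that begins before the study calendar
absorbs its in-study continuation records; the episode date is its first
record (onset). First-ever outcomes (heart failure) keep only the minimum
date, and a pre-study first diagnosis disqualifies all later codes. The
greedy chain is property-tested against an exhaustive merge-until-fixpoint
oracle.

Mixed codes listed under two outcomes (e.g. mixed anxiety-and-depression)
count toward both conditions; the package deliberately does not
deduplicate across outcomes.

## The synthetic generator

`sim_config()` fixes the generating process; its defaults are the study
conditions the package is tested under:

* demographic margins: the 2017 composition of a ~9.9M UK primary-care
  population (9 age bands 11–100, male/female ≈ 50/50, 11 regions,
  ethnicity with ~41% missing);
* chronic prevalence: diabetes 7%, asthma 9%, COPD 4.5%, smoking 25% —
  round UK-primary-care-scale figures chosen once for realism, not fitted;
* registration churn 5%/year and mortality 1%/year as flat hazards;
* contact process: the logistic model above, with at most one contact per
  person-week. The one-per-week cap matches the "proportion of the
  population with a contact" outcome the binomial ITS fits; real
  within-week multiplicity is unknown, and users analysing count-valued
  contacts should note the cap makes binomial and Poisson modes coincide;
* AR(1) noise on the logit scale, initialised at its stationary
  distribution — the generating analogue of the lagged-residual
  adjustment. In aggregated mode the noise is iterated across the excluded
  gap (whose weeks carry no rows), so the generator's autocorrelation
  bridges the gap exactly as the fitted model's lag does.

Acceptance scenarios use baseline weekly contact rates per million from
the pre-interruption levels of the 16 study conditions (5 per million for
unstable angina up to 7863 for COPD exacerbations) and the published step
odds ratios as generating truths. Problem sizes throughout the tests —
166+16 weeks, denominators of $10^6$, 20 replicates for recovery checks,
500 null simulations, populations of a few hundred for individual-record
checks — were chosen as the smallest sizes at which Monte-Carlo error is
comfortably below the tolerances being asserted.

What the generator does **not** emulate: real code dictionaries or
terminology hierarchies (codes are opaque strings in a shared namespace),
practice-level clustering and data-quality windows, demographic
heterogeneity in contact rates (every patient shares $p_t$), seasonality
in registration, or cause-specific mortality. Passing tests therefore
demonstrate correctness of the pipeline's logic and calibration of its
estimators under the stated process — not robustness to real-EHR
messiness.

## Calibration properties and known limitations

The package's own simulations (reproducible via the test suite) establish:

* the step and recovery estimators are unbiased at study scale (absolute
  bias of the step log-OR below 0.01 at denominator $10^6$);
* with uncorrelated extra-binomial logit noise ($\sigma = 0.05$, dispersion
  $\varphi \approx 7$), the scaled-SE 95% CI for the step OR covers at
  roughly 93%: slightly below nominal because the seasonal variation in
  $p_t$ makes the true dispersion mildly heteroscedastic while the
  scaling uses a single pooled $\varphi$;
* with **autocorrelated** noise (AR(1), $\rho = 0.3$), the lagged-residual
  stage does what it is designed to do — final-model residual lag-1
  autocorrelation falls by an order of magnitude — but it does not restore
  the marginal variance of the step contrast, and coverage drops to
  roughly 85%. The post-period mean carries positively correlated noise
  whose variance a pooled dispersion cannot see, and the estimated lag
  coefficient is attenuated (errors-in-variables from binomial noise in
  the residuals plus dynamic-regressor bias). Users should treat step-OR
  intervals under strong autocorrelation as anti-conservative; GEE,
  Newey–West or ARIMA-style corrections are deliberately out of scope
  here.

Other limitations: no uncertainty intervals on cumulative deficits (point
estimates only, matching the presentation convention); small-cell
suppression (`suppress_small_cells()`, threshold 5) applies to published
outputs only — model fitting always uses unsuppressed counts; historical
averages align weeks by ordinal index within year (1–53) because the
Sunday grid drifts against calendar dates, and both mean and median/IQR
summaries are emitted since published figures vary in which they show.
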