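---
title: "Methods: power-outage case-crossover analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: power-outage case-crossover analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical methods implemented by
**outagecco** and the conventions the package fixes where a choice had to
be made. The package estimates the short-term association between
county-level power-outage exposure and daily emergency cardiovascular
(CVD) and respiratory hospitalization counts with a time-stratified
case-crossover design, and ships a synthetic-data generator with known
ground truth so the whole pipeline can be validated end to end.

## 1. Study design

The unit of analysis is the county-day. Each day belongs to exactly one
**stratum** defined by county x year x month x day-of-week
(`build_strata()`), so a case day is compared only against the 3-4 other
same-weekday days of the same county-month. This referent scheme controls,
by design, all confounders that are constant within a county-month
(county composition, seasonal and long-term trends) and weekly patterns
in admissions.

## 2. Exposure construction

Raw exposure data are hourly counts of customers without power per county.
The pipeline (`exposure_table()`) is:

1. **Customer base** (`estimate_customers()`): state customer totals are
   allocated to counties proportionally to county household/establishment
   units, `estimated = round(total x units / sum(units in state))`.
2. **Missingness audit and county exclusion** (`audit_missingness()`,
   `filter_counties()`): counties missing more than 50% of their hours are
   excluded (20% as a sensitivity).
3. **Gap imputation** (`impute_gaps()`): missing runs of at most 4 hours
   are filled by last observation carried forward (LOCF); longer runs and
   leading missingness are set to zero (no outage). A pure zero-fill
   policy is available as a sensitivity.
4. **Run detection** (`detect_runs()`): an hour is "out" when at least 1%
   of estimated customers are without power (the ratio is clamped at 1 if
   the feed over-reports). A maximal run of at least 8 consecutive
   out-hours marks **every calendar day it touches** as exposed.
   Thresholds of 3%/5% and durations of 4/12 hours are produced for the
   secondary analyses; a continuous "daily hours without power" metric
   (hours with >= 1% out, 0-24) supports the threshold-effect analysis.

Conventions fixed here (not dictated by any single authority): the
continuous hours metric always uses the 1% threshold regardless of the
flag threshold in use; run-day attribution defaults to all days a run
touches (`"start_day"` is available); LOCF never crosses a county
boundary and never fills leading missingness.

## 3. Outcomes

Claims are classified by `classify_claims()`: planned admissions never
count; an emergency/urgent claim counts as CVD if any of its **first
five** diagnosis codes starts with I00-I99, respiratory for J00-J99, BOTH
if both. BOTH claims increment both daily counts in `tabulate_claims()`
(the two outcome series are modelled separately, so no double counting
occurs within a model). Codes are upper-cased and stripped of punctuation
before matching; non-ICD-looking codes are ignored with a warning.

## 4. The conditional Poisson model

With counts `y_si` in stratum `s`, day `i`, covariates `x_si` and stratum
intercepts `alpha_s`, the Poisson model `log mu_si = alpha_s + x_si' beta`
conditioned on the stratum totals `N_s = sum_i y_si` has the multinomial
log-likelihood

```
ll(beta) = sum_si y_si eta_si - sum_s N_s log( sum_j exp(eta_sj) ),
eta_si = x_si' beta,
```

which `fit_conditional_poisson()` maximizes by Newton-Raphson with step
halving (score `X'(y - m)`, information `X'diag(m)X - sum_s m_s m_s'/N_s`
with `m` the conditional means). This is exactly equivalent to Poisson
regression with one dummy intercept per stratum; the test suite verifies
agreement with `glm(y ~ X + factor(stratum), family = poisson)` to 1e-6.
Strata with zero total or a single day are uninformative and dropped.
Linear predictors are centered within stratum before exponentiation for
overflow safety. Covariate columns with no within-stratum variation (or
collinear after within-stratum centering) are screened out before
fitting; degeneracy of the *exposure* block is an error instead.

Overdispersion is estimated as the Pearson statistic over
`n - n_strata - k` degrees of freedom (`dispersion()`), and model
comparison uses `qAIC = -2 ll / c_hat + 2k` (`qaic()`) with a common
`c_hat` taken from the richest candidate (`select_model()`); ties break
toward fewer parameters.

## 5. Distributed lags and the cross-basis

Effects over lags 0-6 days are constrained by a natural cubic spline lag
basis (`lag_basis()`): an intercept column plus a spline over lag values,
`df - 2` interior knots at equally spaced quantiles of 0..6 (so 3, 4, 5
df correspond to 1, 2, 3 knots); `df = 7` is the unconstrained identity.
The exposure design is the tensor-product **cross-basis**
(`cross_basis()`): columns `sum_l v_j(x_{t-l}) L[l, k]` for var-dimension
basis `v` and lag basis `L`. For the binary indicator and the linear
hours model `v` is the identity. Per-lag log rate ratios are recovered by
`cb_contrast()`; the cumulative log-RR is their sum with the full
covariance quadratic form (`lag_rr()`, `cumulative_rr()`).

Defaults mirror the main analysis: lag df 5 (CVD) and 3 (respiratory) for
the binary exposure, 4 for the hours metric; temperature enters as a
3-df natural spline x 3-df lag cross-basis; precipitation is linear
(respiratory) or a 2-df spline (CVD); wind speed a 3-df spline; an
optional smoke-day indicator. Natural-spline knots sit at equally spaced
quantiles (`stats::quantile` type 7) with boundary knots at the data
range; for zero-inflated covariates (precipitation) knots falling on the
boundary are recomputed from the interior values so the basis keeps full
rank.

## 6. Secondary and sensitivity analyses

* **Threshold test** (`run_threshold_test()`): eight candidates —
  {linear, 3-df spline} exposure-response x {3,4,5,6} lag df on the
  continuous hours metric — scored by qAIC under a common dispersion. A
  linear winner indicates no duration threshold.
* **Anomalous-day interaction** (`interaction_analysis()`): a hot day
  strictly exceeds the county's 85th reference percentile *and* 24 C;
  a cold day is strictly below the 15th percentile *and* 0 C. The
  interaction model uses a single exposure lag (2 for CVD, 0 for
  respiratory — the largest main-analysis lags) with the meteorological
  covariates retained.
* **Stratified effect modification** (`stratified_emm()`): independent
  refits per subgroup.
* **Sensitivity suite** (`run_sensitivity_suite()`): gap policy x
  county-exclusion cutoff x smoke adjustment, with differences from the
  main configuration tabulated.
* **Attributable burden** (`attributable()`): `AF = (RR - 1)/RR` applied
  to hospitalizations in the exposed window. Published excess totals are
  not reproducible without the restricted person-day denominators, so the
  window is an explicit parameter (`"day0"` or `"lag0_6"`), and interval
  endpoints propagate the RR confidence limits.

## 7. The synthetic generator

`simulate_study()` draws, from one root seed (every component uses a
fixed offset of it, so tables are reproducible independently):

* a **daily exposure calendar** per county from a two-state Markov chain
  calibrated so the stationary prevalence and lag-1 autocorrelation hit
  their targets exactly (defaults 0.013 and 0.2; infeasible combinations
  error at configuration time);
* an **hourly outage series** realizing each exposed day as one
  contiguous within-day run of at least 8 hours (length 8 + geometric,
  capped at 24) with an out-fraction of at least 1% of customers, plus
  decoy sub-8-hour runs on 1% of unexposed days, sub-threshold background
  noise, and MCAR missing blocks (rate 0.03/county-day, mean 30 h, ~3.75%
  of hours) that the exposure pipeline must survive;
* **weather** with sinusoidal seasonal temperature, and a -2 C / +1.5 m/s
  shift on outage days so exposure and weather are genuinely confounded;
* **counts**: Poisson with log rate = county baseline (uniform on
  log[3, 12]) + centered county x month x weekday effects (sd 0.1) + the
  distributed-lag exposure effect + a lagged quadratic temperature
  effect; `noise = FALSE` returns the expected surface for noise-free
  validation;
* optionally **claims** that tabulate back to the counts exactly
  (qualifying code uniform over dx1-dx5; decoys with the qualifying code
  only in dx6; planned-admission extras).

`lag_curve_in_span()` projects a target lag curve onto the span of a
chosen lag basis (optionally pinning one lag's value exactly), so
simulation truths are representable by the constrained estimator and
recovery/coverage experiments measure sampling error, not approximation
bias. Fixture sizes used by the validation suite (40-100 counties x 365
days; a 5 x 60 "tiny" smoke-test fixture with elevated exposure
prevalence 0.15) are package choices balancing Monte-Carlo precision
against runtime; the Wald test's finite-sample calibration depends on the
number of exposed county-days, and the calibration experiments run at the
generator's default scale (100 counties).

## 8. Worked example

```{r example, eval = FALSE}
library(outagecco)

sim <- simulate_study(fixture_config("paper-like"))
rows <- sim_rows(sim, outcome = "cvd")
fit <- cco_fit(rows)
summary(fit)
plot(fit)

lag_rr(fit)          # per-lag rate ratios
cumulative_rr(fit)   # 7-day cumulative

# continuous hours metric and threshold test
rh <- sim_rows(sim, outcome = "cvd", exposure_col = "hours_out")
run_threshold_test(rh)$best

# attributable burden
et <- exposure_table(sim$series,
                     estimate_customers(sim$base$county_units,
                                        sim$base$state_totals))
attributable(cumulative_rr(fit), sim$counts,
             et[et$exposed_8h_p1, c("county_id", "date")], outcome = "cvd")
```

## 9. Limitations

County-level exposure misclassifies household-level outage; the customer
base is an allocation estimate; LOCF assumes short gaps continue the last
state; the case-crossover design addresses slowly varying confounding but
not day-scale confounders beyond the modelled weather terms. The
synthetic generator is a validation instrument, not an emulation of any
real feed: its effect sizes, missingness process and weather coupling are
chosen to exercise the estimator, and analyses of real data should revisit
each convention above.
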