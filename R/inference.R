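# From fitted coefficients to lag-specific and cumulative rate ratios,
# secondary/sensitivity/effect-modification analyses and attributable
# hospitalizations.

#' Lag-specific rate ratios from a fitted case-crossover model
#'
#' Maps the exposure cross-basis coefficient block back to the seven per-lag
#' log rate ratios for the contrast `x1` versus `x0` (exposed vs unexposed
#' for the binary indicator; `x0 + 1` hour is a per-hour contrast for the
#' continuous metric). Standard errors come from the quadratic form with the
#' model covariance; intervals are Wald on the log scale.
#'
#' @param fit a [cco_fit()] object.
#' @param x1,x0 exposure levels contrasted.
#' @param level confidence level.
#' @return data.frame of class `lag_rr_curve` with lag, log_rr, se, rr, lo,
#'   hi; the cumulative summary is attached as attribute `"cumulative"`.
#' @export
lag_rr <- function(fit, x1 = 1, x0 = 0, level = 0.95) {
  idx <- fit$blocks$exposure
  A <- cb_contrast(fit$exposure_meta, x1, x0)
  b <- fit$coefficients[idx]
  V <- fit$vcov[idx, idx, drop = FALSE]
  if (any(!is.finite(V))) stop("singular covariance for the exposure block")
  est <- as.vector(A %*% b)
  se <- sqrt(pmax(0, rowSums((A %*% V) * A)))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  out <- data.frame(lag = 0:6, log_rr = est, se = se,
                    rr = exp(est), lo = exp(est - zq * se),
                    hi = exp(est + zq * se))
  a <- colSums(A)
  cum_est <- sum(est)
  cum_se <- sqrt(max(0, as.vector(t(a) %*% V %*% a)))
  attr(out, "cumulative") <- list(log_rr = cum_est, se = cum_se,
                                  rr = exp(cum_est),
                                  lo = exp(cum_est - zq * cum_se),
                                  hi = exp(cum_est + zq * cum_se))
  attr(out, "contrast") <- c(x1 = x1, x0 = x0)
  attr(out, "level") <- level
  class(out) <- c("lag_rr_curve", "data.frame")
  out
}

#' @export
print.lag_rr_curve <- function(x, digits = 4, ...) {
  cat("Lag rate ratios (contrast ", attr(x, "contrast")["x1"], " vs ",
      attr(x, "contrast")["x0"], "):\n", sep = "")
  print(round(as.data.frame(x)[, c("lag", "rr", "lo", "hi")], digits))
  cum <- attr(x, "cumulative")
  cat(sprintf("cumulative RR %.*f (%.*f, %.*f)\n", digits, cum$rr,
              digits, cum$lo, digits, cum$hi))
  invisible(x)
}

#' Cumulative rate ratio over lags 0-6
#'
#' The cumulative log-RR is the sum of the per-lag log-RRs (so the
#' cumulative RR is their product); its variance is the full quadratic form
#' over the lag-summed contrast.
#'
#' @param fit a [cco_fit()] object or a [lag_rr()] curve.
#' @param ... passed to [lag_rr()] when `fit` is a model.
#' @return list rr, lo, hi, log_rr, se.
#' @export
cumulative_rr <- function(fit, ...) {
  curve <- if (inherits(fit, "lag_rr_curve")) fit else lag_rr(fit, ...)
  attr(curve, "cumulative")
}

#' Exposure-response curve for the continuous hours metric
#'
#' Rate ratios at each grid value of daily hours without power, relative to
#' zero hours, per lag and cumulatively.
#'
#' @param fit a [cco_fit()] with `exposure = "hours"`.
#' @param hours grid of exposure values (default 0:24).
#' @param lag single lag to report, or `NULL` for the cumulative curve.
#' @param level confidence level.
#' @return data.frame hours, rr, lo, hi (for the chosen lag or cumulative).
#' @export
exposure_response <- function(fit, hours = 0:24, lag = NULL, level = 0.95) {
  idx <- fit$blocks$exposure
  b <- fit$coefficients[idx]
  V <- fit$vcov[idx, idx, drop = FALSE]
  zq <- stats::qnorm(1 - (1 - level) / 2)
  res <- lapply(hours, function(h) {
    A <- cb_contrast(fit$exposure_meta, h, 0)
    if (is.null(lag)) {
      a <- colSums(A)
    } else {
      a <- A[lag + 1L, ]
    }
    est <- sum(a * b)
    se <- sqrt(max(0, as.vector(t(a) %*% V %*% a)))
    c(est = est, se = se)
  })
  est <- vapply(res, `[[`, numeric(1), "est")
  se <- vapply(res, `[[`, numeric(1), "se")
  data.frame(hours = hours, rr = exp(est),
             lo = exp(est - zq * se), hi = exp(est + zq * se),
             log_rr = est, se = se)
}

#' Threshold test for the continuous hours metric
#'
#' Fits the eight candidate models — {linear, 3-df natural spline}
#' exposure-response x {3, 4, 5, 6} lag-basis df — scores them with qAIC
#' under a common dispersion estimated from the richest candidate, and
#' reports the winner. A linear winner indicates no threshold in the
#' exposure-response.
#'
#' @param rows assembled rows with a continuous exposure history
#'   (`exposure_col = "hours_out"`).
#' @param lag_dfs candidate lag-basis df values.
#' @param ... further arguments to [cco_fit()].
#' @return list: `table` (8-row qAIC table with form and lag df), `best`
#'   (winning form and lag df), `c_hat`, `best_fit`.
#' @export
run_threshold_test <- function(rows, lag_dfs = 3:6, ...) {
  cands <- expand.grid(form = c("linear", "ns"), lag_df = lag_dfs,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  fits <- vector("list", nrow(cands))
  names(fits) <- paste0(cands$form, "_lag", cands$lag_df)
  for (i in seq_len(nrow(cands))) {
    fits[[i]] <- tryCatch(
      cco_fit(rows, exposure = "hours", exposure_fun = cands$form[i],
              exposure_df = 3L, lag_df = cands$lag_df[i], ...),
      error = function(e) NULL)
  }
  sel <- select_model(fits)
  tab <- cbind(cands, sel$table[, c("k", "loglik", "qaic", "converged")])
  best_i <- match(sel$best, names(fits))
  list(table = tab,
       best = list(form = cands$form[best_i], lag_df = cands$lag_df[best_i]),
       c_hat = sel$c_hat,
       best_fit = fits[[best_i]])
}

#' Stratified effect-modification analysis
#'
#' Fits the same model independently within each subgroup (separate strata,
#' separate dispersion — fully stratified refits) and reports the lag RR
#' curves side by side. For county-level durable-medical-equipment use, pass
#' the quartile-1 and quartile-4 subsets to contrast them.
#'
#' @param rows_list named list of assembled row tables, one per subgroup.
#' @param ... arguments passed to [cco_fit()].
#' @return list: `curves` (named list of [lag_rr()] results, NULL where a
#'   subgroup could not be fit), `table` (long data.frame subgroup x lag),
#'   `failed` (names of subgroups without informative strata).
#' @export
stratified_emm <- function(rows_list, ...) {
  stopifnot(is.list(rows_list), !is.null(names(rows_list)))
  curves <- lapply(names(rows_list), function(nm) {
    tryCatch(lag_rr(cco_fit(rows_list[[nm]], ...)),
             error = function(e) {
               message("subgroup ", nm, " not fit: ", conditionMessage(e))
               NULL
             })
  })
  names(curves) <- names(rows_list)
  ok <- !vapply(curves, is.null, logical(1))
  tab <- do.call(rbind, lapply(names(curves)[ok], function(nm) {
    d <- as.data.frame(curves[[nm]])
    cbind(subgroup = nm, d[, c("lag", "rr", "lo", "hi")])
  }))
  list(curves = curves, table = tab, failed = names(curves)[!ok])
}

#' Interaction with anomalously hot or cold days
#'
#' Models a single lag of exposure (the lag with the largest main-analysis
#' effect: lag 2 for CVD, lag 0 for respiratory), a binary anomalous-day
#' term and their interaction, keeping the meteorological covariates of the
#' main model. Reports the exposure RR on ordinary days
#' (`exp(beta_outage)`) and on modifier days
#' (`exp(beta_outage + beta_interaction)`).
#'
#' @param rows assembled rows carrying hot_day/cold_day flags.
#' @param modifier `"hot_day"` or `"cold_day"`.
#' @param lag single exposure lag (default: 2 for CVD rows, 0 for
#'   respiratory rows).
#' @param level confidence level.
#' @param ... further arguments to [fit_conditional_poisson()].
#' @return data.frame with rows "ordinary days" and "modifier days": rr, lo,
#'   hi; the fit and an overlap flag are attached as attributes.
#' @export
interaction_analysis <- function(rows, modifier = c("hot_day", "cold_day"),
                                 lag = NULL, level = 0.95, ...) {
  modifier <- match.arg(modifier)
  outcome <- attr(rows, "outcome")
  if (is.null(lag)) lag <- if (identical(outcome, "resp")) 0L else 2L
  x <- as.numeric(rows[[paste0("exp_l", lag)]])
  m <- as.numeric(rows[[modifier]])
  overlap <- sum(x * m) > 0
  if (!overlap)
    warning("no exposure on ", modifier,
            " days; interaction term cannot be identified")
  TM <- as.matrix(rows[, paste0("tmax_l", 0:6)])
  cb_tmp <- cross_basis(TM, var_kind = "ns", var_df = 3L, lag_df = 3L)
  Xw <- natural_spline_basis(rows$wind_ms, df = 3L)
  colnames(Xw) <- paste0("wind_ns", seq_len(ncol(Xw)))
  Xp <- if (identical(outcome, "cvd")) {
    B <- natural_spline_basis(rows$precip_mm, df = 2L)
    colnames(B) <- paste0("precip_ns", seq_len(ncol(B)))
    B
  } else matrix(rows$precip_mm, ncol = 1, dimnames = list(NULL, "precip"))
  X <- cbind(outage = x, modifier = m, outage_x_mod = x * m,
             cb_tmp$X, Xp, Xw)
  # retained temperature spline and modifier indicator are not collinear
  # (a threshold indicator is outside the spline span), but screen anyway
  des <- list(y = rows$y, X = X, strata = rows$stratum,
              blocks = list(exposure = 1:3))
  des <- screen_columns(des)
  fit <- fit_conditional_poisson(des$y, des$X, des$strata, ...)
  b <- fit$coefficients
  V <- fit$vcov
  zq <- stats::qnorm(1 - (1 - level) / 2)
  est <- c(b["outage"], b["outage"] + b["outage_x_mod"])
  se <- c(sqrt(V["outage", "outage"]),
          sqrt(V["outage", "outage"] + V["outage_x_mod", "outage_x_mod"] +
                 2 * V["outage", "outage_x_mod"]))
  out <- data.frame(days = c("ordinary", "modifier"),
                    rr = exp(est), lo = exp(est - zq * se),
                    hi = exp(est + zq * se), row.names = NULL)
  attr(out, "fit") <- fit
  attr(out, "modifier") <- modifier
  attr(out, "lag") <- lag
  attr(out, "overlap") <- overlap
  out
}

#' Attributable fraction and excess hospitalizations
#'
#' Applies the population attributable fraction `AF = (RR - 1)/RR` — with
#' `RR` the cumulative 7-day rate ratio — to the hospitalizations occurring
#' in the designated post-outage window. Interval endpoints propagate the RR
#' confidence limits.
#'
#' @param cumulative list with rr, lo, hi (from [cumulative_rr()]), or a
#'   [lag_rr()] curve.
#' @param counts daily outcome counts (county_id, date and the outcome
#'   column).
#' @param exposed data.frame of exposed county-days (county_id, date), e.g.
#'   from [detect_runs()] or the TRUE rows of an [exposure_table()] flag.
#' @param outcome `"cvd"` or `"resp"`.
#' @param window `"day0"` (default: hospitalizations on the outage day) or
#'   `"lag0_6"` (the seven-day window following each outage day).
#' @return list of class `attributable_result`: rr, af, exposed_hosp,
#'   excess, excess_lo, excess_hi, window.
#' @export
attributable <- function(cumulative, counts, exposed,
                         outcome = c("cvd", "resp"),
                         window = c("day0", "lag0_6")) {
  outcome <- match.arg(outcome)
  window <- match.arg(window)
  if (inherits(cumulative, "lag_rr_curve"))
    cumulative <- attr(cumulative, "cumulative")
  rr <- cumulative$rr
  stopifnot(rr > 0)
  ycol <- paste0(outcome, "_count")
  ekey <- key_county_date(exposed$county_id, as.Date(exposed$date))
  if (window == "lag0_6") {
    grid <- expand.grid(i = seq_len(nrow(exposed)), l = 0:6)
    ekey <- unique(key_county_date(exposed$county_id[grid$i],
                                   as.Date(exposed$date)[grid$i] + grid$l))
  }
  sel <- key_county_date(counts$county_id, as.Date(counts$date)) %in% ekey
  n_hosp <- sum(counts[[ycol]][sel])
  af <- function(r) (r - 1) / r
  out <- list(rr = rr, af = af(rr), exposed_hosp = n_hosp,
              excess = af(rr) * n_hosp,
              excess_lo = af(cumulative$lo) * n_hosp,
              excess_hi = af(cumulative$hi) * n_hosp,
              window = window)
  class(out) <- "attributable_result"
  out
}

#' @export
print.attributable_result <- function(x, ...) {
  cat(sprintf("Cumulative RR %.4f -> attributable fraction %.4f\n", x$rr, x$af))
  cat(sprintf("%d hospitalizations in the %s exposure window\n",
              x$exposed_hosp, x$window))
  cat(sprintf("Excess: %.1f (%.1f, %.1f)\n", x$excess, x$excess_lo, x$excess_hi))
  invisible(x)
}

#' Paired sensitivity analyses of the exposure-construction choices
#'
#' Re-runs the main fit under each combination of gap policy (LOCF then
#' zero, vs zero-fill) x county-missingness exclusion (50 percent vs 20
#' percent) x smoke-day adjustment (off/on), and tabulates the lag RRs and
#' their differences from the main configuration.
#'
#' @param sim a study bundle ([simulate_study()] or [read_fixture()]).
#' @param outcome `"cvd"` or `"resp"`.
#' @param exposure_col exposure flag used for the fits.
#' @param ... further arguments to [cco_fit()].
#' @return list: `table` (lag RRs per configuration), `diff` (RR difference
#'   from the main configuration), `configs`.
#' @export
run_sensitivity_suite <- function(sim, outcome = "cvd",
                                  exposure_col = "exposed_8h_p1", ...) {
  base <- estimate_customers(sim$base$county_units, sim$base$state_totals)
  combos <- expand.grid(policy = c("locf_then_zero", "zero"),
                        exclusion = c(0.50, 0.20),
                        smoke = c(FALSE, TRUE),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  combos$name <- paste0(combos$policy, "_excl", combos$exclusion * 100,
                        ifelse(combos$smoke, "_smoke", ""))
  res <- vector("list", nrow(combos))
  weather <- flag_smoke(sim$weather)
  for (i in seq_len(nrow(combos))) {
    spec <- exposure_spec(gap_fill_policy = combos$policy[i],
                          county_missing_exclusion = combos$exclusion[i])
    et <- exposure_table(sim$series, base, spec)
    rows <- assemble_rows(sim$counts, et, weather, outcome = outcome,
                          exposure_col = exposure_col)
    fit <- cco_fit(rows, smoke = combos$smoke[i], ...)
    rr <- as.data.frame(lag_rr(fit))
    res[[i]] <- data.frame(config = combos$name[i], lag = rr$lag, rr = rr$rr,
                           lo = rr$lo, hi = rr$hi,
                           n_counties = length(attr(et, "retained")),
                           stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, res)
  main <- res[[1]]
  diffs <- do.call(rbind, lapply(res, function(d)
    data.frame(config = d$config, lag = d$lag, rr_diff = d$rr - main$rr)))
  list(table = tab, diff = diffs, configs = combos)
}
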