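# Replicate harness for the Monte-Carlo acceptance properties: build the
# analysis design once from a configuration, keep the expected-count
# surface, and redraw Poisson counts per replicate so each replicate costs
# one conditional fit, not a full pipeline run.

replicate_harness <- function(config, outcome = "cvd",
                              exposure_col = "exposed_8h_p1", ...) {
  sim <- simulate_study(config)
  base <- estimate_customers(sim$base$county_units, sim$base$state_totals)
  et <- exposure_table(sim$series, base)
  weather <- flag_smoke(sim$weather)
  rows <- assemble_rows(sim$counts, et, weather, outcome = outcome,
                        exposure_col = exposure_col)
  des <- outagecco:::screen_columns(outagecco:::build_design(rows, ...))
  mu_df <- gen_counts(config, exposure = sim$calendar + 0,
                      weather = sim$weather, truth = sim$truth, noise = FALSE)
  ycol <- paste0(outcome, "_count")
  m <- match(paste(rows$county_id, rows$date),
             paste(mu_df$county_id, mu_df$date))
  stopifnot(!anyNA(m))
  A <- cb_contrast(des$exposure_meta)
  list(des = des, mu = mu_df[[ycol]][m], truth = sim$truth,
       contrast = A, exposure_idx = des$blocks$exposure, et = et, sim = sim)
}

# One replicate: redraw counts, refit, return the lag-1 log-RR, its SE and
# convergence. Returns NAs when the refit fails outright.
replicate_lag1 <- function(h) {
  y <- stats::rpois(length(h$mu), h$mu)
  fit <- tryCatch(
    fit_conditional_poisson(y, h$des$X, h$des$strata),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged)
    return(c(est = NA_real_, se = NA_real_))
  b <- fit$coefficients[h$exposure_idx]
  V <- fit$vcov[h$exposure_idx, h$exposure_idx, drop = FALSE]
  a <- h$contrast[2, ]
  c(est = sum(a * b), se = sqrt(max(0, as.vector(t(a) %*% V %*% a))))
}

# Harness for the threshold-test property: continuous hours exposure with a
# truly linear per-hour effect; the eight candidate designs are built once.
threshold_harness <- function(n_counties = 15L, n_days = 365L,
                              per_hour_log_rr = 0.002, seed = 1L) {
  theta <- lag_curve_in_span(c(0.3, 1, 0.6, 0.3, 0.1, 0, 0), lag_df = 3L,
                             fix_lag = 1L, fix_value = per_hour_log_rr)
  cfg <- sim_config(n_counties = n_counties, n_days = n_days,
                    target_exposure_prevalence = 0.15,
                    true_lag_log_rr = theta, seed = seed)
  base <- gen_customer_base(cfg)
  series <- gen_outage_series(cfg)
  est <- estimate_customers(base$county_units, base$state_totals)
  et <- exposure_table(series, est, exposure_spec())
  M <- hours_matrix(et, cfg)
  weather <- gen_weather(cfg)
  truth <- gen_truth(cfg)
  mu_df <- gen_counts(cfg, exposure = M, weather = weather, truth = truth,
                      noise = FALSE)
  rows <- assemble_rows(mu_df, et, flag_smoke(weather), outcome = "cvd",
                        exposure_col = "hours_out")
  cands <- expand.grid(form = c("linear", "ns"), lag_df = 3:6,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  designs <- lapply(seq_len(nrow(cands)), function(i)
    outagecco:::screen_columns(outagecco:::build_design(
      rows, outcome = "cvd", exposure = "hours",
      exposure_fun = cands$form[i], exposure_df = 3L,
      lag_df = cands$lag_df[i])))
  m <- match(paste(rows$county_id, rows$date),
             paste(mu_df$county_id, mu_df$date))
  list(cands = cands, designs = designs, mu = mu_df$cvd_count[m],
       strata = rows$stratum)
}

# One threshold-test replicate: redraw counts, fit all candidates, and
# return the form of the qAIC winner (common dispersion from the richest).
replicate_threshold_winner <- function(h) {
  y <- stats::rpois(length(h$mu), h$mu)
  fits <- lapply(h$designs, function(d)
    tryCatch(fit_conditional_poisson(y, d$X, h$strata),
             error = function(e) NULL))
  names(fits) <- paste0(h$cands$form, "_", h$cands$lag_df)
  sel <- suppressWarnings(select_model(fits))
  h$cands$form[match(sel$best, names(fits))]
}
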