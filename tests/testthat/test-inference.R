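test_that("unconstrained lag curve equals the raw coefficient block", {
  sim <- tiny_sim()
  rows <- sim_rows(sim, outcome = "cvd")
  fit <- cco_fit(rows, lag_df = 7L)
  rr <- lag_rr(fit)
  b <- coef(fit)[fit$blocks$exposure]
  expect_equal(rr$log_rr, unname(b))
  V <- vcov(fit)[fit$blocks$exposure, fit$blocks$exposure]
  expect_equal(rr$se, unname(sqrt(diag(V))))
  # cumulative log-RR is the sum with the full covariance quadratic form
  cum <- cumulative_rr(fit)
  expect_equal(cum$log_rr, sum(b))
  expect_equal(cum$se, sqrt(sum(V)))
  expect_equal(cum$rr, prod(rr$rr))
})

test_that("constrained lag curve is the basis transform of the coefficients", {
  sim <- tiny_sim()
  rows <- sim_rows(sim, outcome = "cvd")
  fit <- cco_fit(rows, lag_df = 4L)
  rr <- lag_rr(fit)
  L <- fit$exposure_meta$L
  expect_equal(rr$log_rr,
               as.vector(L %*% coef(fit)[fit$blocks$exposure]))
  # confidence level propagates
  rr90 <- lag_rr(fit, level = 0.90)
  expect_true(all(rr90$lo >= rr$lo - 1e-12))
  expect_true(all(rr90$hi <= rr$hi + 1e-12))
})

test_that("exposure-response for the linear hours model scales linearly", {
  sim <- tiny_sim()
  rh <- sim_rows(sim, outcome = "cvd", exposure_col = "hours_out")
  fit <- cco_fit(rh, exposure = "hours", exposure_fun = "linear")
  er <- exposure_response(fit, hours = c(0, 1, 12, 24), lag = 1L)
  expect_equal(er$rr[1], 1)
  expect_equal(log(er$rr[3]), 12 * log(er$rr[2]), tolerance = 1e-10)
  expect_equal(log(er$rr[4]), 24 * log(er$rr[2]), tolerance = 1e-10)
})

test_that("attributable fraction identities and window accounting hold", {
  counts <- data.frame(county_id = c("A", "A", "A", "B"),
                       date = as.Date("2018-06-01") + c(0, 1, 2, 0),
                       cvd_count = c(10L, 20L, 30L, 5L),
                       resp_count = 0L, stringsAsFactors = FALSE)
  exposed <- data.frame(county_id = "A", date = as.Date("2018-06-01"),
                        stringsAsFactors = FALSE)
  # AF(1) = 0: a null RR attributes nothing
  a0 <- attributable(list(rr = 1, lo = 1, hi = 1), counts, exposed, "cvd")
  expect_equal(a0$af, 0)
  expect_equal(a0$excess, 0)
  # AF(1.04) = 1 - 1/1.04 = 0.03846...
  a1 <- attributable(list(rr = 1.04, lo = 1.01, hi = 1.07), counts, exposed,
                     "cvd")
  expect_equal(a1$af, 0.04 / 1.04)
  expect_equal(a1$af, 0.03846, tolerance = 1e-4)
  expect_equal(a1$exposed_hosp, 10L)             # day-0 window
  expect_equal(a1$excess, 10 * 0.04 / 1.04)
  expect_equal(a1$excess_lo, 10 * 0.01 / 1.01)
  expect_equal(a1$excess_hi, 10 * 0.07 / 1.07)
  # the 7-day window accumulates the following days without double counting
  a2 <- attributable(list(rr = 1.04, lo = 1.01, hi = 1.07), counts,
                     rbind(exposed, data.frame(county_id = "A",
                                               date = as.Date("2018-06-02"))),
                     "cvd", window = "lag0_6")
  expect_equal(a2$exposed_hosp, 60L)
  expect_output(print(a1), "attributable fraction")
})

test_that("interaction analysis reproduces its coefficient algebra", {
  # a full year so the climatology has enough reference days and summer
  # hot days overlap outage exposure
  sim <- simulate_study(fixture_config("tiny", n_days = 365L))
  clim <- climatology_percentiles(sim$weather)
  rows <- sim_rows(sim, outcome = "cvd", climatology = clim)
  ia <- interaction_analysis(rows, modifier = "hot_day")
  fit <- attr(ia, "fit")
  b <- fit$coefficients
  expect_equal(ia$rr[1], exp(unname(b["outage"])))
  expect_equal(ia$rr[2], exp(unname(b["outage"] + b["outage_x_mod"])))
  expect_equal(attr(ia, "lag"), 2L)               # CVD default lag
  rows_r <- sim_rows(sim, outcome = "resp", climatology = clim)
  ia_r <- interaction_analysis(rows_r, modifier = "cold_day")
  expect_equal(attr(ia_r, "lag"), 0L)             # respiratory default lag
})

test_that("stratified subgroup fits run independently", {
  sim <- tiny_sim()
  rows <- sim_rows(sim, outcome = "cvd")
  half <- split(seq_len(nrow(rows)), rows$county_id %in%
                  unique(rows$county_id)[1:2])
  rl <- list(g1 = rows[half[["TRUE"]], ], g2 = rows[half[["FALSE"]], ])
  for (nm in names(rl)) {
    attr(rl[[nm]], "outcome") <- "cvd"
    attr(rl[[nm]], "exposure_col") <- "exposed_8h_p1"
  }
  emm <- suppressMessages(stratified_emm(rl))
  done <- setdiff(names(rl), emm$failed)
  expect_gt(length(done), 0)
  expect_true(all(emm$table$subgroup %in% done))
  expect_equal(sum(emm$table$subgroup == done[1]), 7L)
})

test_that("threshold test scores all eight candidates with a common c-hat", {
  sim <- tiny_sim()
  rh <- sim_rows(sim, outcome = "cvd", exposure_col = "hours_out")
  tt <- run_threshold_test(rh)
  expect_equal(nrow(tt$table), 8L)
  expect_setequal(tt$table$form, c("linear", "ns"))
  expect_setequal(tt$table$lag_df, 3:6)
  rich <- which.max(tt$table$k)
  expect_true(tt$best$form %in% c("linear", "ns"))
  # qAIC values are computed from the reported common dispersion
  expect_equal(tt$table$qaic,
               -2 * tt$table$loglik / tt$c_hat + 2 * tt$table$k)
  expect_equal(qaic(tt$best_fit, tt$c_hat), min(tt$table$qaic))
})

test_that("sensitivity suite compares configurations against the main fit", {
  sim <- tiny_sim()
  ss <- run_sensitivity_suite(sim)
  expect_equal(nrow(ss$configs), 8L)
  expect_equal(nrow(ss$table), 8L * 7L)
  # the main configuration has zero difference to itself
  expect_equal(ss$diff$rr_diff[ss$diff$config == ss$configs$name[1]],
               rep(0, 7))
})
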