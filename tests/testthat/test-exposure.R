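mk_series <- function(customers_out, county = "C0001",
                      origin = as.Date("2018-01-01")) {
  n <- length(customers_out)
  out <- data.frame(
    county_id = county,
    timestamp = as.POSIXct(paste(origin, "00:00:00"), tz = "UTC") +
      3600 * (seq_len(n) - 1L),
    customers_out = as.integer(customers_out),
    stringsAsFactors = FALSE)
  attr(out, "origin") <- origin
  out
}

mk_base <- function(est, county = "C0001") {
  data.frame(county_id = county, estimated_customers = as.integer(est),
             stringsAsFactors = FALSE)
}

test_that("customer estimation allocates state totals proportionally", {
  cu <- data.frame(county_id = c("A", "B", "C"),
                   state_id = c("S1", "S1", "S2"),
                   county_units = c(30L, 10L, 50L), stringsAsFactors = FALSE)
  st <- data.frame(state_id = c("S1", "S2"),
                   total_customers = c(4000L, 9000L), stringsAsFactors = FALSE)
  est <- estimate_customers(cu, st)
  expect_equal(est$estimated_customers, c(3000L, 1000L, 9000L))
  # rounding happens per county; totals agree up to rounding
  expect_error(estimate_customers(cu, st[1, ]), "S2")
  st$total_customers[1] <- 0L
  expect_error(estimate_customers(cu, st), "positive")
  # large state totals must not overflow integer arithmetic
  big <- estimate_customers(
    data.frame(county_id = "A", state_id = "S", county_units = 1L),
    data.frame(state_id = "S", total_customers = 2000000000L))
  expect_equal(big$estimated_customers, 2000000000L)
})

test_that("gap imputation follows the LOCF-then-zero rule exactly", {
  x <- c(5, 5, NA, NA, NA, 9, NA, NA, NA, NA, NA, 2, rep(0, 12))
  sr <- mk_series(x)
  imp <- impute_gaps(sr, exposure_spec(locf_max_gap_hours = 4L))
  # 3-hour gap carried forward from 5; 5-hour gap zero-filled
  expect_equal(imp$customers_out[3:5], c(5L, 5L, 5L))
  expect_equal(imp$customers_out[7:11], rep(0L, 5))
  fills <- attr(imp, "fill_counts")
  expect_equal(fills$imputed_hours, 3L)
  expect_equal(fills$zeroed_hours, 5L)
  # leading missingness is always zero-filled (nothing to carry)
  sr2 <- mk_series(c(NA, NA, 7, rep(0, 21)))
  imp2 <- impute_gaps(sr2)
  expect_equal(imp2$customers_out[1:2], c(0L, 0L))
  # the "zero" policy zero-fills everything
  imp3 <- impute_gaps(sr, exposure_spec(gap_fill_policy = "zero"))
  expect_equal(imp3$customers_out[3:5], rep(0L, 3))
  expect_false(anyNA(imp3$customers_out))
})

test_that("run detection honors threshold, duration and day attribution", {
  est <- 1000L
  # 8 consecutive hours at exactly 1%: qualifies (>= is inclusive)
  x <- rep(0L, 48); x[5:12] <- 10L
  d <- detect_runs(mk_series(x), mk_base(est))
  expect_equal(nrow(d), 1L)
  expect_equal(d$date, as.Date("2018-01-01"))
  # 7 hours does not qualify
  x2 <- rep(0L, 48); x2[5:11] <- 10L
  expect_equal(nrow(detect_runs(mk_series(x2), mk_base(est))), 0L)
  # just below the 1% threshold does not qualify
  x3 <- rep(0L, 48); x3[5:12] <- 9L
  expect_equal(nrow(detect_runs(mk_series(x3), mk_base(est))), 0L)
  # a run spanning midnight marks both days under all_days attribution
  x4 <- rep(0L, 48); x4[20:31] <- 50L
  d4 <- detect_runs(mk_series(x4), mk_base(est))
  expect_equal(d4$date, as.Date(c("2018-01-01", "2018-01-02")))
  d4s <- detect_runs(mk_series(x4), mk_base(est),
                     exposure_spec(run_day_attribution = "start_day"))
  expect_equal(d4s$date, as.Date("2018-01-01"))
  # customers_out above the estimate is clamped with a warning, not an error
  x5 <- rep(0L, 24); x5[1:9] <- 2000L
  expect_warning(d5 <- detect_runs(mk_series(x5), mk_base(est)), "clamped")
  expect_equal(nrow(d5), 1L)
  # missing hours are rejected until imputed
  x6 <- c(NA, rep(0L, 23))
  expect_error(detect_runs(mk_series(x6), mk_base(est)), "impute_gaps")
})

test_that("run detection agrees with the brute-force oracle", {
  set.seed(301)
  est <- 1000L
  for (i in 1:200) {
    n_days <- sample(2:5, 1)
    x <- random_hourly_series(n_days, est)
    sr <- mk_series(x)
    d <- detect_runs(sr, mk_base(est))
    got <- as.integer(d$date - as.Date("2018-01-01")) + 1L
    want <- oracle_exposed_days(x / est >= 0.01, 8L)
    expect_equal(got, want)
  }
})

test_that("daily hours-out counts qualifying hours at the 1% threshold", {
  est <- 1000L
  x <- rep(0L, 48)
  x[c(1, 2, 3, 30)] <- 10L   # 3 hours day 1, 1 hour day 2
  x[5] <- 9L                 # below threshold, not counted
  h <- daily_hours_out(mk_series(x), mk_base(est))
  expect_equal(h$hours_out, c(3L, 1L))
  expect_equal(h$date, as.Date(c("2018-01-01", "2018-01-02")))
})

test_that("county exclusion applies the missingness cutoff", {
  x_ok <- c(rep(NA, 10), rep(0L, 38))       # 10/48 missing
  x_bad <- c(rep(NA, 30), rep(0L, 18))      # 30/48 missing
  sr <- rbind(mk_series(x_ok, "C0001"), mk_series(x_bad, "C0002"))
  attr(sr, "origin") <- as.Date("2018-01-01")
  aud <- audit_missingness(sr)
  expect_equal(aud$frac_missing, c(10, 30) / 48)
  keep <- filter_counties(aud, exposure_spec())
  expect_equal(as.character(keep), "C0001")
  expect_equal(attr(keep, "n_excluded"), 1L)
  # the 20% sensitivity cutoff drops both
  expect_error(filter_counties(aud,
                               exposure_spec(county_missing_exclusion = 0.2)),
               "no counties retained")
})

test_that("exposure_table produces consistent nested flags and bookkeeping", {
  sim <- tiny_sim()
  base <- estimate_customers(sim$base$county_units, sim$base$state_totals)
  et <- exposure_table(sim$series, base)
  cfg <- sim$config
  expect_equal(nrow(et), cfg$n_counties * cfg$n_days -
                 sum(!sim$base$county_units$county_id %in%
                       attr(et, "retained")) * cfg$n_days)
  # monotonicity: stricter thresholds and longer durations flag fewer days
  expect_true(all(et$exposed_8h_p1 >= et$exposed_8h_p3))
  expect_true(all(et$exposed_8h_p3 >= et$exposed_8h_p5))
  expect_true(all(et$exposed_4h_p1 >= et$exposed_8h_p1))
  expect_true(all(et$exposed_8h_p1 >= et$exposed_12h_p1))
  # an 8h-exposed day belongs to a run, so it or a neighbor has >= 8 hours out
  expect_true(all(et$hours_out >= 0 & et$hours_out <= 24))
  # fill bookkeeping adds up to the county's audited missingness
  aud <- attr(et, "audit")
  per_county <- tapply(et$imputed_hours + et$missing_hours, et$county_id, sum)
  expect_equal(as.integer(per_county[aud$county_id]), aud$n_missing)
})

test_that("exposure_table matches detect_runs day for day", {
  sim <- tiny_sim()
  base <- estimate_customers(sim$base$county_units, sim$base$state_totals)
  spec <- exposure_spec()
  et <- exposure_table(sim$series, base, spec)
  imp <- impute_gaps(sim$series[sim$series$county_id %in%
                                  attr(et, "retained"), , drop = FALSE], spec)
  attr(imp, "origin") <- attr(sim$series, "origin")
  d <- detect_runs(imp, base, spec)
  flagged <- paste(et$county_id, et$date)[et$exposed_8h_p1]
  expect_setequal(flagged, paste(d$county_id, d$date))
})
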