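test_that("strata are county x year x month x weekday", {
  d <- as.Date(c("2018-01-01", "2018-01-08", "2018-01-02", "2018-02-05",
                 "2019-01-07"))
  s <- build_strata(rep("C1", 5), d)
  expect_equal(s[1], "C1|2018|1|1")        # 2018-01-01 was a Monday
  expect_equal(s[1], s[2])                 # same weekday, same month
  expect_false(s[1] == s[3])               # Tuesday differs
  expect_false(s[1] == s[4])               # February differs
  expect_false(s[1] == s[5])               # 2019 differs
  expect_false(build_strata("C1", d[1]) == build_strata("C2", d[1]))
})

test_that("climatology percentiles use the recorded quantile convention", {
  set.seed(11)
  ref <- data.frame(county_id = rep("C1", 365),
                    tmax_c = stats::rnorm(365, 15, 8),
                    stringsAsFactors = FALSE)
  p <- climatology_percentiles(ref)
  expect_equal(p$p_hot, stats::quantile(ref$tmax_c, 0.85, names = FALSE,
                                        type = 7))
  expect_equal(p$p_cold, stats::quantile(ref$tmax_c, 0.15, names = FALSE,
                                         type = 7))
  expect_equal(attr(p, "quantile_type"), 7L)
  # counties with too little data get flagged, not silently dropped
  ref2 <- rbind(ref, data.frame(county_id = "C2", tmax_c = 20))
  expect_warning(p2 <- climatology_percentiles(ref2), "insufficient")
  expect_false(p2$ok[p2$county_id == "C2"])
  expect_true(is.na(p2$p_hot[p2$county_id == "C2"]))
})

test_that("anomalous-day flags need both the percentile and absolute cutoff", {
  pct <- data.frame(county_id = "C1", p_cold = 2, p_hot = 22, n = 365,
                    ok = TRUE, stringsAsFactors = FALSE)
  w <- data.frame(county_id = "C1",
                  date = as.Date("2018-07-01") + 0:4,
                  tmax_c = c(23, 25, 22, 1, -1), stringsAsFactors = FALSE)
  f <- flag_anomalous(w, pct)
  # 23 beats the percentile (22) but not the 24 C absolute cutoff
  expect_equal(f$hot_day, c(FALSE, TRUE, FALSE, FALSE, FALSE))
  # 1 beats neither cutoff strictly (cold needs < 0 and < percentile)
  expect_equal(f$cold_day, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  # strictness at the boundary: equal to the cutoff is not anomalous
  w2 <- data.frame(county_id = "C1", date = as.Date("2018-07-06"),
                   tmax_c = 24, stringsAsFactors = FALSE)
  pct2 <- pct; pct2$p_hot <- 20
  expect_false(flag_anomalous(w2, pct2)$hot_day)
  # counties without climatology get FALSE flags and are reported
  w3 <- data.frame(county_id = "C9", date = as.Date("2018-07-01"),
                   tmax_c = 40, stringsAsFactors = FALSE)
  f3 <- flag_anomalous(w3, pct)
  expect_false(f3$hot_day)
  expect_equal(attr(f3, "no_climatology"), "C9")
})

test_that("smoke flags come from strictly positive concentrations", {
  w <- data.frame(smoke_ugm3 = c(0, 0.1, 5, NA))
  expect_warning(f <- flag_smoke(w), "missing")
  expect_equal(f$smoke_day, c(FALSE, TRUE, TRUE, FALSE))
  expect_error(flag_smoke(data.frame(smoke_ugm3 = -1)), "negative")
})

test_that("assemble_rows aligns lag histories and drops the right rows", {
  sim <- tiny_sim()
  base <- estimate_customers(sim$base$county_units, sim$base$state_totals)
  et <- exposure_table(sim$series, base)
  weather <- flag_smoke(sim$weather)
  rows <- assemble_rows(sim$counts, et, weather, outcome = "cvd")
  expect_true(all(c("y", paste0("exp_l", 0:6), paste0("tmax_l", 0:6),
                    "stratum", "precip_mm", "wind_ms") %in% names(rows)))
  # no date earlier than day 7 of the study can have a full lookback
  expect_true(all(rows$date >= min(et$date) + 6))
  # lag columns are shifted copies of the exposure series
  i <- which(rows$county_id == rows$county_id[1])[8]
  for (l in 1:6) {
    prev_key <- paste(rows$county_id[i], rows$date[i] - l)
    j <- which(paste(et$county_id, et$date) == prev_key)
    expect_equal(rows[[paste0("exp_l", l)]][i],
                 as.numeric(et$exposed_8h_p1[j]))
    k <- which(paste(weather$county_id, weather$date) == prev_key)
    expect_equal(rows[[paste0("tmax_l", l)]][i], weather$tmax_c[k])
  }
  # every retained stratum has a positive total and at least two days
  tot <- tapply(rows$y, rows$stratum, sum)
  expect_true(all(tot > 0))
  expect_true(all(table(rows$stratum) >= 2))
  # a gap in the dates is a hard error, not silent misalignment
  cut <- sim$counts[sim$counts$date != min(et$date) + 20, , drop = FALSE]
  et_cut <- et[et$date != min(et$date) + 20, , drop = FALSE]
  expect_error(assemble_rows(cut, et_cut, weather, outcome = "cvd"),
               "non-contiguous")
})

test_that("assemble_rows respects the requested outcome and exposure column", {
  sim <- tiny_sim()
  base <- estimate_customers(sim$base$county_units, sim$base$state_totals)
  et <- exposure_table(sim$series, base)
  weather <- flag_smoke(sim$weather)
  r_cvd <- assemble_rows(sim$counts, et, weather, outcome = "cvd")
  r_resp <- assemble_rows(sim$counts, et, weather, outcome = "resp")
  key <- paste(r_cvd$county_id, r_cvd$date)
  m <- match(key, paste(sim$counts$county_id, sim$counts$date))
  expect_equal(r_cvd$y, sim$counts$cvd_count[m])
  expect_false(identical(r_cvd$y, r_resp$y))
  r_h <- assemble_rows(sim$counts, et, weather, outcome = "cvd",
                       exposure_col = "hours_out")
  expect_true(any(r_h$exp_l0 > 1))          # continuous hours, not 0/1
  expect_error(assemble_rows(sim$counts, et, weather, outcome = "cvd",
                             exposure_col = "nope"), "exposure column")
})
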