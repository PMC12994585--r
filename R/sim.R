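# Synthetic study generator: county-hour outage feeds, customer bases,
# daily meteorology and daily hospitalization counts with known truth.

#' Configuration for the synthetic study generator
#'
#' Bundles every parameter of the data-generating process: the daily outage
#' occurrence process (a two-state Markov chain calibrated to a target
#' county-day prevalence and lag-1 autocorrelation), the within-day hourly
#' outage structure, block-wise missingness of the hourly feed, seasonal
#' meteorology (optionally shifted on outage days), and the log-linear count
#' model (county baselines, county x month x weekday stratum effects, a
#' distributed-lag outage effect over lags 0-6 and a nonlinear temperature
#' effect).
#'
#' @param n_counties number of counties.
#' @param n_days length of the study window in days.
#' @param start_date first calendar day of the window.
#' @param target_exposure_prevalence target marginal probability that a
#'   county-day is exposed (8+ consecutive hours with >= 1 percent of
#'   customers out). Default 0.013.
#' @param target_lag1_autocorr target lag-1 autocorrelation of the daily
#'   exposure indicator. Default 0.2.
#' @param missing_block_rate probability per county-day that a missing block
#'   starts that day.
#' @param missing_block_hours mean length (hours, geometric) of a missing
#'   block.
#' @param baseline_log_rate_range range (log scale) of per-county baseline
#'   daily hospitalization counts.
#' @param true_lag_log_rr numeric length-7 vector of true log rate ratios at
#'   lags 0-6 for the CVD outcome (per unit of exposure: per exposed day for
#'   the binary indicator, per hour for continuous exposure).
#' @param true_lag_log_rr_resp as `true_lag_log_rr`, for the respiratory
#'   outcome; defaults to the CVD curve.
#' @param temp_effect_spec list with elements `coef`, `ref_c`, `scale_c` and
#'   `lag_weights` (length 7): the true temperature effect on the log rate is
#'   `coef * sum_l lag_weights[l] * ((tmax[day - l] - ref_c)/scale_c)^2`.
#' @param run_length_geom_p geometric parameter for outage run length
#'   (length = 8 + geometric, capped at 24 hours).
#' @param out_frac_rate rate of the exponential used to draw the fraction of
#'   customers out during a run: fraction = 0.01 * exp(Exp(rate)).
#' @param short_run_rate probability per unexposed county-day of a short
#'   (3-7 hour, above-threshold) decoy outage.
#' @param background_rate fraction of hours carrying small sub-threshold
#'   customers-out noise.
#' @param weather list of meteorology parameters (see defaults).
#' @param resp_log_rate_offset log offset of respiratory vs CVD baselines.
#' @param stratum_sd standard deviation of the county x month x weekday
#'   stratum effects (centered within county).
#' @param counties_per_state number of counties assigned to each state.
#' @param mean_county_units mean number of household/establishment units per
#'   county.
#' @param customers_per_unit state customer total per unit.
#' @param seed integer; fully determines all generated outputs.
#'
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_counties = 100L,
                       n_days = 365L,
                       start_date = as.Date("2018-01-01"),
                       target_exposure_prevalence = 0.013,
                       target_lag1_autocorr = 0.2,
                       missing_block_rate = 0.03,
                       missing_block_hours = 30,
                       baseline_log_rate_range = log(c(3, 12)),
                       true_lag_log_rr = rep(0, 7),
                       true_lag_log_rr_resp = NULL,
                       temp_effect_spec = list(coef = 0.03, ref_c = 18, scale_c = 10,
                                               lag_weights = c(0.50, 0.25, 0.12,
                                                               0.07, 0.03, 0.02, 0.01)),
                       run_length_geom_p = 0.30,
                       out_frac_rate = 1.1,
                       short_run_rate = 0.01,
                       background_rate = 0.01,
                       weather = list(),
                       resp_log_rate_offset = log(805 / 1351),
                       stratum_sd = 0.1,
                       counties_per_state = 10L,
                       mean_county_units = 20000,
                       customers_per_unit = 1.05,
                       seed = 1L) {
  stopifnot(n_counties >= 1, n_days >= 1)
  if (!(target_exposure_prevalence > 0 && target_exposure_prevalence < 1))
    stop("target_exposure_prevalence must be in (0, 1)")
  if (length(true_lag_log_rr) != 7L)
    stop("true_lag_log_rr must have length 7 (lags 0-6)")
  if (is.null(true_lag_log_rr_resp)) true_lag_log_rr_resp <- true_lag_log_rr
  if (length(true_lag_log_rr_resp) != 7L)
    stop("true_lag_log_rr_resp must have length 7 (lags 0-6)")
  w_default <- list(tmax_mean_c = 15, tmax_amp_c = 10, tmax_sd_c = 4,
                    peak_doy = 196, tmax_shift_c = -2, wind_shift_ms = 1.5,
                    precip_prob = 0.35, precip_shape = 0.7, precip_scale = 8,
                    wind_shape = 4, wind_scale = 1,
                    smoke_prob = 0.03, smoke_shape = 1, smoke_scale = 10)
  w_default[names(weather)] <- weather
  mc <- markov_from_targets(target_exposure_prevalence, target_lag1_autocorr)
  cfg <- list(n_counties = as.integer(n_counties), n_days = as.integer(n_days),
              start_date = as.Date(start_date),
              target_exposure_prevalence = target_exposure_prevalence,
              target_lag1_autocorr = target_lag1_autocorr,
              markov = mc,
              missing_block_rate = missing_block_rate,
              missing_block_hours = missing_block_hours,
              baseline_log_rate_range = baseline_log_rate_range,
              true_lag_log_rr = true_lag_log_rr,
              true_lag_log_rr_resp = true_lag_log_rr_resp,
              temp_effect_spec = temp_effect_spec,
              run_length_geom_p = run_length_geom_p,
              out_frac_rate = out_frac_rate,
              short_run_rate = short_run_rate,
              background_rate = background_rate,
              weather = w_default,
              resp_log_rate_offset = resp_log_rate_offset,
              stratum_sd = stratum_sd,
              counties_per_state = as.integer(counties_per_state),
              mean_county_units = mean_county_units,
              customers_per_unit = customers_per_unit,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# Transition probabilities of the stationary two-state daily chain with
# marginal prevalence pi and lag-1 autocorrelation rho:
#   p01 = P(exposed | prior unexposed) = pi (1 - rho)
#   p11 = P(exposed | prior exposed)   = rho + pi (1 - rho)
markov_from_targets <- function(pi, rho) {
  p01 <- pi * (1 - rho)
  p11 <- rho + pi * (1 - rho)
  if (p01 < 0 || p01 > 1 || p11 < 0 || p11 > 1)
    stop(sprintf(paste0("unattainable (prevalence, autocorrelation) pair: ",
                        "with prevalence %.4g the feasible autocorrelation ",
                        "range is [%.4g, 1]"),
                 pi, -pi / (1 - pi)))
  list(p01 = p01, p11 = p11)
}

# Evaluate an expression under a temporary RNG state so that each generator
# stage is deterministic in config$seed and independent of call order.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

sim_dates <- function(config) config$start_date + seq_len(config$n_days) - 1L

county_ids <- function(n) sprintf("C%04d", seq_len(n))

#' Generate the synthetic customer-base tables
#'
#' Counties are assigned to states in blocks; each county receives a number of
#' household/establishment units, and each state a total customer count
#' proportional to its summed units.
#'
#' @param config a [sim_config()].
#' @return list with `county_units` (county_id, state_id, county_units) and
#'   `state_totals` (state_id, total_customers).
#' @export
gen_customer_base <- function(config) {
  with_seed(config$seed + 2L, {
    n <- config$n_counties
    cid <- county_ids(n)
    sid <- sprintf("S%03d", ((seq_len(n) - 1L) %/% config$counties_per_state) + 1L)
    units <- pmax(50L, as.integer(round(stats::rlnorm(
      n, log(config$mean_county_units), 0.8))))
    cu <- data.frame(county_id = cid, state_id = sid, county_units = units,
                     stringsAsFactors = FALSE)
    st <- stats::aggregate(county_units ~ state_id, cu, sum)
    st$total_customers <- as.integer(round(st$county_units * config$customers_per_unit))
    st$county_units <- NULL
    list(county_units = cu, state_totals = st)
  })
}

#' Generate the realized daily outage calendar
#'
#' Draws, per county, the stationary two-state Markov chain whose marginal
#' prevalence and lag-1 autocorrelation are the configured targets. This
#' calendar is the ground-truth exposure used by [gen_counts()]; the hourly
#' feed produced by [gen_outage_series()] realizes it as contiguous
#' above-threshold runs of 8+ hours.
#'
#' @param config a [sim_config()].
#' @return logical matrix, counties x days.
#' @export
gen_exposure_calendar <- function(config) {
  with_seed(config$seed + 1L, {
    C <- config$n_counties; D <- config$n_days
    p01 <- config$markov$p01; p11 <- config$markov$p11
    E <- matrix(FALSE, C, D,
                dimnames = list(county_ids(C), as.character(sim_dates(config))))
    E[, 1L] <- stats::runif(C) < config$target_exposure_prevalence
    if (D > 1L) for (d in 2:D) {
      p <- ifelse(E[, d - 1L], p11, p01)
      E[, d] <- stats::runif(C) < p
    }
    E
  })
}

#' Generate hourly county-level customers-without-power series
#'
#' Expands the daily outage calendar into hourly counts: each exposed
#' county-day carries one contiguous run of at least 8 hours during which at
#' least 1 percent of the county's customers are out (run length 8 +
#' geometric, capped at 24; out-fraction 0.01 * exp(Exponential)). Unexposed
#' days may carry short (3-7 h) above-threshold decoy runs and sparse
#' sub-threshold background noise. Missing blocks (customers_out = NA) are
#' injected independently of outage state, in geometric-length blocks.
#'
#' @param config a [sim_config()].
#' @param base optional customer base from [gen_customer_base()] (regenerated
#'   from the config seed if omitted).
#' @param calendar optional calendar from [gen_exposure_calendar()]
#'   (regenerated if omitted).
#' @return data.frame with columns county_id, timestamp (POSIXct, UTC used as
#'   a stand-in for county-local clock time), customers_out (integer, NA for
#'   missing feed hours); ordered by county then hour.
#' @export
gen_outage_series <- function(config, base = NULL, calendar = NULL) {
  if (is.null(base)) base <- gen_customer_base(config)
  if (is.null(calendar)) calendar <- gen_exposure_calendar(config)
  est <- estimate_customers(base$county_units, base$state_totals)
  cust <- est$estimated_customers[match(rownames(calendar), est$county_id)]
  C <- config$n_counties; D <- config$n_days; H <- D * 24L
  with_seed(config$seed + 3L, {
    v <- integer(C * H)
    # main runs on exposed days
    idx <- which(calendar)                    # column-major: county varies fastest
    if (length(idx)) {
      ci <- ((idx - 1L) %% C) + 1L
      di <- ((idx - 1L) %/% C) + 1L
      len <- pmin(24L, 8L + stats::rgeom(length(idx), config$run_length_geom_p))
      start <- floor(stats::runif(length(idx)) * (24L - len + 1L))
      frac <- pmin(0.8, 0.01 * exp(stats::rexp(length(idx), config$out_frac_rate)))
      n_out <- pmin(cust[ci], pmax(ceiling(0.01 * cust[ci]), round(frac * cust[ci])))
      h0 <- (ci - 1L) * H + (di - 1L) * 24L + start       # 0-based
      pos <- sequence(len, from = h0 + 1L)
      v[pos] <- rep.int(as.integer(n_out), len)
    }
    # short decoy runs on unexposed days (above threshold, < 8 h, away from
    # midnight so they cannot merge with a neighbouring day's run)
    un <- which(!calendar)
    un <- un[stats::runif(length(un)) < config$short_run_rate]
    if (length(un)) {
      ci <- ((un - 1L) %% C) + 1L
      di <- ((un - 1L) %/% C) + 1L
      len <- sample(3:7, length(un), replace = TRUE)
      start <- sample(4:16, length(un), replace = TRUE)
      frac <- pmin(0.8, 0.01 * exp(stats::rexp(length(un), config$out_frac_rate)))
      n_out <- pmin(cust[ci], pmax(ceiling(0.01 * cust[ci]), round(frac * cust[ci])))
      pos <- sequence(len, from = (ci - 1L) * H + (di - 1L) * 24L + start + 1L)
      v[pos] <- rep.int(as.integer(n_out), len)
    }
    # sparse sub-threshold background noise
    nbg <- round(config$background_rate * length(v))
    if (nbg > 0) {
      bg <- sample.int(length(v), nbg)
      bg <- bg[v[bg] == 0L]
      if (length(bg)) {
        bci <- ((bg - 1L) %/% H) + 1L
        val <- pmin(as.integer(ceiling(0.01 * cust[bci])) - 1L,
                    pmax(0L, as.integer(round(stats::runif(length(bg)) * 0.008 * cust[bci]))))
        v[bg] <- pmax(0L, val)
      }
    }
    # MCAR missing blocks
    nb <- which(matrix(stats::runif(C * D) < config$missing_block_rate, C, D))
    if (length(nb)) {
      ci <- ((nb - 1L) %% C) + 1L
      di <- ((nb - 1L) %/% C) + 1L
      start <- sample(0:23, length(nb), replace = TRUE)
      len <- pmin(72L, 1L + stats::rgeom(length(nb), 1 / config$missing_block_hours))
      h0 <- (ci - 1L) * H + (di - 1L) * 24L + start
      len <- pmin(len, ci * H - h0)           # clip at the county block end
      pos <- sequence(len, from = h0 + 1L)
      v[pos] <- NA_integer_
    }
    ts0 <- as.POSIXct(paste(config$start_date, "00:00:00"), tz = "UTC")
    out <- data.frame(
      county_id = rep(county_ids(C), each = H),
      timestamp = rep(ts0 + 3600 * (seq_len(H) - 1L), times = C),
      customers_out = v,
      stringsAsFactors = FALSE)
    attr(out, "origin") <- config$start_date
    out
  })
}

#' Generate daily county meteorology
#'
#' Maximal temperature follows a sinusoidal annual cycle plus Gaussian noise;
#' precipitation is zero-inflated gamma; wind speed is gamma. On outage days
#' temperature is shifted down and wind up by the configured amounts, so that
#' outages occur on colder, windier days.
#'
#' @param config a [sim_config()].
#' @param calendar optional outage calendar (regenerated from the config seed
#'   if omitted); pass a zero matrix to decouple weather from exposure.
#' @return data.frame county_id, date, tmax_c, precip_mm, wind_ms, smoke_ugm3.
#' @export
gen_weather <- function(config, calendar = NULL) {
  if (is.null(calendar)) calendar <- gen_exposure_calendar(config)
  C <- config$n_counties; D <- config$n_days
  w <- config$weather
  dates <- sim_dates(config)
  doy <- as.integer(format(dates, "%j"))
  with_seed(config$seed + 4L, {
    seas <- w$tmax_mean_c + w$tmax_amp_c * cos(2 * pi * (doy - w$peak_doy) / 365.25)
    tmax <- rep(seas, each = C) + stats::rnorm(C * D, sd = w$tmax_sd_c)
    tmax <- tmax + w$tmax_shift_c * as.numeric(calendar)
    precip <- ifelse(stats::runif(C * D) < w$precip_prob,
                     stats::rgamma(C * D, w$precip_shape, scale = w$precip_scale), 0)
    wind <- stats::rgamma(C * D, w$wind_shape, scale = w$wind_scale) +
      w$wind_shift_ms * as.numeric(calendar)
    smoke <- ifelse(stats::runif(C * D) < w$smoke_prob,
                    stats::rgamma(C * D, w$smoke_shape, scale = w$smoke_scale), 0)
    data.frame(county_id = rep(county_ids(C), times = D),
               date = rep(dates, each = C),
               tmax_c = round(tmax, 2),
               precip_mm = round(precip, 2),
               wind_ms = round(wind, 2),
               smoke_ugm3 = round(smoke, 2),
               stringsAsFactors = FALSE)
  })
}

#' Generate the ground-truth parameter set
#'
#' @param config a [sim_config()].
#' @return list of class `sim_truth`: per-county baseline log rates, stratum
#'   effects (county x year-month x weekday, centered within county), the true
#'   lag log-RR vectors, and the temperature-effect specification.
#' @export
gen_truth <- function(config) {
  dates <- sim_dates(config)
  ym <- unique(format(dates, "%Y-%m"))
  wd <- 1:7
  cid <- county_ids(config$n_counties)
  with_seed(config$seed + 5L, {
    baseline <- stats::runif(config$n_counties,
                             config$baseline_log_rate_range[1],
                             config$baseline_log_rate_range[2])
    names(baseline) <- cid
    grid <- expand.grid(county_id = cid, yearmon = ym, weekday = wd,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    eff <- stats::rnorm(nrow(grid), sd = config$stratum_sd)
    # center within county so stratum effects carry no county-level signal
    eff <- eff - stats::ave(eff, grid$county_id)
    grid$effect <- eff
    out <- list(baseline_log_rate = baseline,
                stratum_effects = grid,
                true_lag_log_rr = config$true_lag_log_rr,
                true_lag_log_rr_resp = config$true_lag_log_rr_resp,
                temp_effect_spec = config$temp_effect_spec,
                config = config)
    class(out) <- "sim_truth"
    out
  })
}

# True log-rate surface (counties x days) for one outcome. exposure is a
# numeric counties x days matrix (0/1 indicator or hours); lag history before
# the window start is padded with zeros.
sim_log_rate <- function(config, truth, exposure, weather, outcome = c("cvd", "resp")) {
  outcome <- match.arg(outcome)
  C <- config$n_counties; D <- config$n_days
  dates <- sim_dates(config)
  theta <- if (outcome == "cvd") truth$true_lag_log_rr else truth$true_lag_log_rr_resp
  base <- truth$baseline_log_rate[county_ids(C)]
  if (outcome == "resp") base <- base + config$resp_log_rate_offset
  eta <- matrix(base, C, D)
  # stratum effects
  se <- truth$stratum_effects
  key_grid <- paste(rep(county_ids(C), times = D),
                    rep(format(dates, "%Y-%m"), each = C),
                    rep(as.integer(format(dates, "%u")), each = C), sep = "|")
  key_se <- paste(se$county_id, se$yearmon, se$weekday, sep = "|")
  eta <- eta + matrix(se$effect[match(key_grid, key_se)], C, D)
  # distributed-lag exposure effect (zero-padded history)
  tm <- matrix(weather$tmax_c[match(key_county_date(rep(county_ids(C), times = D),
                                                    rep(dates, each = C)),
                                    key_county_date(weather$county_id, weather$date))],
               C, D)
  ts <- truth$temp_effect_spec
  for (l in 0:6) {
    if (l < D) {
      cols <- (l + 1L):D
      eta[, cols] <- eta[, cols] + theta[l + 1L] * exposure[, cols - l]
      eta[, cols] <- eta[, cols] +
        ts$coef * ts$lag_weights[l + 1L] *
          ((tm[, cols - l] - ts$ref_c) / ts$scale_c)^2
    }
  }
  eta
}

key_county_date <- function(county, date) paste(county, as.character(date), sep = "|")

#' Generate daily outcome counts from the log-linear truth
#'
#' Counts are Poisson with log rate = county baseline + county x month x
#' weekday stratum effect + the distributed-lag exposure effect + the lagged
#' nonlinear temperature effect. Lag histories preceding the window start are
#' padded with zeros (the affected first six days are flagged via the
#' `"padded_days"` attribute).
#'
#' @param config a [sim_config()].
#' @param exposure numeric counties x days matrix driving the lag effect
#'   (the 0/1 calendar, or an hours matrix for continuous-exposure studies);
#'   defaults to the regenerated calendar.
#' @param weather data.frame from [gen_weather()].
#' @param truth a [gen_truth()] object (regenerated if omitted).
#' @param noise if `FALSE`, return the expected counts (non-integer) instead
#'   of Poisson draws; used for noise-free validation fixtures.
#' @return data.frame county_id, date, cvd_count, resp_count.
#' @export
gen_counts <- function(config, exposure = NULL, weather = NULL, truth = NULL,
                       noise = TRUE) {
  if (is.null(exposure)) exposure <- gen_exposure_calendar(config) + 0
  if (is.null(weather)) weather <- gen_weather(config)
  if (is.null(truth)) truth <- gen_truth(config)
  storage.mode(exposure) <- "double"
  C <- config$n_counties; D <- config$n_days
  dates <- sim_dates(config)
  mu_cvd <- exp(sim_log_rate(config, truth, exposure, weather, "cvd"))
  mu_resp <- exp(sim_log_rate(config, truth, exposure, weather, "resp"))
  with_seed(config$seed + 6L, {
    if (noise) {
      y1 <- stats::rpois(C * D, as.vector(mu_cvd))
      y2 <- stats::rpois(C * D, as.vector(mu_resp))
    } else {
      y1 <- as.vector(mu_cvd); y2 <- as.vector(mu_resp)
    }
    out <- data.frame(county_id = rep(county_ids(C), times = D),
                      date = rep(dates, each = C),
                      cvd_count = y1, resp_count = y2,
                      stringsAsFactors = FALSE)
    attr(out, "padded_days") <- dates[seq_len(min(6L, D))]
    out
  })
}

#' Expand daily counts into individual claim records
#'
#' Emits one emergency/urgent claim per counted hospitalization, with a
#' qualifying ICD-10 code (I-prefix for CVD, J-prefix for respiratory) placed
#' uniformly among the first five diagnosis positions and non-cardiorespiratory
#' filler codes elsewhere. Also adds decoy claims whose only qualifying code
#' sits in position 6, and planned-admission claims; neither should be counted
#' by the outcomes module, so tabulating the generated claims round-trips to
#' the input counts.
#'
#' @param counts data.frame from [gen_counts()] (integer counts).
#' @param config a [sim_config()].
#' @return data.frame claim_id, county_id, date, admission_type, dx1..dx10.
#' @export
gen_claims <- function(counts, config) {
  cvd_codes <- c("I10", "I110", "I21", "I509", "I639", "I48")
  resp_codes <- c("J189", "J441", "J449", "J9601", "J459", "J069")
  filler <- c("E119", "N179", "Z515", "K219", "M545", "F0390", "G309", "D649", "A419")
  with_seed(config$seed + 7L, {
    mk <- function(n, county, date, codes, pos_range, type) {
      if (n == 0L) return(NULL)
      dx <- matrix(sample(filler, 10L * n, replace = TRUE), n, 10L)
      pos <- if (length(pos_range) == 1L) rep.int(pos_range, n) else
        sample(pos_range, n, replace = TRUE)
      dx[cbind(seq_len(n), pos)] <- sample(codes, n, replace = TRUE)
      out <- data.frame(county_id = county, date = date,
                        admission_type = type, stringsAsFactors = FALSE)
      colnames(dx) <- paste0("dx", 1:10)
      cbind(out, as.data.frame(dx, stringsAsFactors = FALSE))
    }
    n1 <- sum(counts$cvd_count); n2 <- sum(counts$resp_count)
    r1 <- rep(seq_len(nrow(counts)), counts$cvd_count)
    r2 <- rep(seq_len(nrow(counts)), counts$resp_count)
    typ1 <- sample(c("emergency", "urgent"), n1, replace = TRUE, prob = c(0.6, 0.4))
    typ2 <- sample(c("emergency", "urgent"), n2, replace = TRUE, prob = c(0.6, 0.4))
    real1 <- mk(n1, counts$county_id[r1], counts$date[r1], cvd_codes, 1:5, typ1)
    real2 <- mk(n2, counts$county_id[r2], counts$date[r2], resp_codes, 1:5, typ2)
    nd <- stats::rbinom(1L, n1 + n2, 0.05)
    rd <- sample.int(nrow(counts), nd, replace = TRUE)
    decoy <- mk(nd, counts$county_id[rd], counts$date[rd],
                c(cvd_codes, resp_codes), 6L, "emergency")
    np <- stats::rbinom(1L, n1 + n2, 0.05)
    rp <- sample.int(nrow(counts), np, replace = TRUE)
    planned <- mk(np, counts$county_id[rp], counts$date[rp],
                  c(cvd_codes, resp_codes), 1:5, "planned")
    claims <- rbind(real1, real2, decoy, planned)
    if (is.null(claims)) {
      claims <- data.frame(county_id = character(), date = as.Date(character()),
                           admission_type = character(), stringsAsFactors = FALSE)
      for (j in 1:10) claims[[paste0("dx", j)]] <- character()
    }
    claims <- cbind(claim_id = sprintf("CLM%07d", seq_len(nrow(claims))), claims,
                    stringsAsFactors = FALSE)
    rownames(claims) <- NULL
    claims
  })
}

#' Generate a full synthetic study bundle in memory
#'
#' @param config a [sim_config()].
#' @param claims also expand counts into claim records (can be large).
#' @return list with elements `base`, `calendar`, `series`, `weather`,
#'   `counts`, `truth`, and optionally `claims`.
#' @export
simulate_study <- function(config, claims = FALSE) {
  base <- gen_customer_base(config)
  calendar <- gen_exposure_calendar(config)
  series <- gen_outage_series(config, base, calendar)
  weather <- gen_weather(config, calendar)
  truth <- gen_truth(config)
  counts <- gen_counts(config, calendar + 0, weather, truth)
  out <- list(config = config, base = base, calendar = calendar, series = series,
              weather = weather, counts = counts, truth = truth)
  if (claims) out$claims <- gen_claims(counts, config)
  out
}

#' Lag curve inside the span of a constrained lag basis
#'
#' Projects a target 7-vector of per-lag log rate ratios onto the column space
#' of the natural-spline lag basis with `lag_df` degrees of freedom, then
#' rescales so the value at `fix_lag` equals `fix_value` exactly. Useful for
#' building simulation truths that the constrained estimator can represent
#' without approximation bias.
#'
#' @param target numeric length-7 target shape (lags 0-6).
#' @param lag_df lag-basis degrees of freedom (2-7).
#' @param fix_lag,fix_value optionally pin the curve at one lag.
#' @return numeric length-7 lag curve.
#' @export
lag_curve_in_span <- function(target, lag_df, fix_lag = NULL, fix_value = NULL) {
  L <- lag_basis(lag_df)
  gamma <- solve(crossprod(L), crossprod(L, target))
  curve <- as.vector(L %*% gamma)
  if (!is.null(fix_lag)) {
    stopifnot(!is.null(fix_value), fix_lag %in% 0:6)
    curve <- curve * (fix_value / curve[fix_lag + 1L])
  }
  curve
}

#' Named fixture configurations
#'
#' Three standard study conditions: `"null"` (no outage effect), `"paper-like"`
#' (a lag curve peaking at lag 1 with log-RR 0.02, positive at lags 0-3 and
#' near-null at lags 4-6, constructed inside the span of the 5-df lag basis),
#' and `"tiny"` (5 counties x 60 days for fast end-to-end tests).
#'
#' @param name one of `"null"`, `"paper-like"`, `"tiny"`.
#' @param ... overrides passed to [sim_config()].
#' @return a [sim_config()].
#' @export
fixture_config <- function(name = c("null", "paper-like", "tiny"), ...) {
  name <- match.arg(name)
  dots <- list(...)
  defaults <- switch(name,
    "null" = list(n_counties = 40L, n_days = 365L, true_lag_log_rr = rep(0, 7)),
    "paper-like" = list(
      n_counties = 40L, n_days = 365L,
      true_lag_log_rr = lag_curve_in_span(
        c(0.010, 0.020, 0.014, 0.008, 0.002, 0, 0), lag_df = 5L,
        fix_lag = 1L, fix_value = 0.02)),
    "tiny" = list(n_counties = 5L, n_days = 60L,
                  # dense exposure so 60-day strata still identify the lag
                  # basis in smoke tests
                  target_exposure_prevalence = 0.15,
                  true_lag_log_rr = c(0.01, 0.02, 0.01, 0.005, 0, 0, 0)))
  defaults[names(dots)] <- dots
  do.call(sim_config, defaults)
}

#' Write a fixture bundle to disk
#'
#' Writes the delimited tables (outage hours with ISO-8601 timestamps,
#' weather, counts, claims, customer base), the ground truth (JSON) and a
#' manifest (YAML, config + seed) to a directory; [read_fixture()] reloads it.
#'
#' @param config a [sim_config()] or a fixture name for [fixture_config()].
#' @param dir target directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @param claims include the expanded claims table.
#' @return `dir`, invisibly.
#' @export
make_fixture <- function(config, dir, overwrite = FALSE, claims = TRUE) {
  if (is.character(config)) config <- fixture_config(config)
  if (dir.exists(dir) && length(dir(dir)) && !overwrite)
    stop("fixture directory exists and is non-empty; use overwrite = TRUE")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_study(config, claims = claims)
  hrs <- sim$series
  hrs$timestamp <- format(hrs$timestamp, "%Y-%m-%dT%H:%M:%S")
  utils::write.csv(hrs, file.path(dir, "outage_hours.csv"), row.names = FALSE,
                   na = "")
  utils::write.csv(sim$weather, file.path(dir, "weather.csv"), row.names = FALSE)
  utils::write.csv(sim$counts, file.path(dir, "counts.csv"), row.names = FALSE)
  utils::write.csv(sim$base$county_units, file.path(dir, "county_units.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$base$state_totals, file.path(dir, "state_totals.csv"),
                   row.names = FALSE)
  if (claims)
    utils::write.csv(sim$claims, file.path(dir, "claims.csv"), row.names = FALSE)
  truth <- sim$truth
  truth$config <- NULL
  jsonlite::write_json(
    list(baseline_log_rate = as.list(truth$baseline_log_rate),
         stratum_effects = truth$stratum_effects,
         true_lag_log_rr = truth$true_lag_log_rr,
         true_lag_log_rr_resp = truth$true_lag_log_rr_resp,
         temp_effect_spec = truth$temp_effect_spec),
    file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  cfg <- unclass(config)
  cfg$start_date <- as.character(cfg$start_date)
  yaml::write_yaml(cfg, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Reload a fixture bundle written by [make_fixture()]
#'
#' @param dir fixture directory.
#' @return list mirroring [simulate_study()] output (without the calendar
#'   matrix; the truth tables are restored from JSON).
#' @export
read_fixture <- function(dir) {
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  man$start_date <- as.Date(man$start_date)
  man$true_lag_log_rr <- as.numeric(man$true_lag_log_rr)
  man$true_lag_log_rr_resp <- as.numeric(man$true_lag_log_rr_resp)
  class(man) <- "sim_config"
  hrs <- utils::read.csv(file.path(dir, "outage_hours.csv"),
                         stringsAsFactors = FALSE,
                         colClasses = c(customers_out = "integer"))
  hrs$timestamp <- as.POSIXct(hrs$timestamp, format = "%Y-%m-%dT%H:%M:%S",
                              tz = "UTC")
  attr(hrs, "origin") <- man$start_date
  weather <- utils::read.csv(file.path(dir, "weather.csv"), stringsAsFactors = FALSE)
  weather$date <- as.Date(weather$date)
  counts <- utils::read.csv(file.path(dir, "counts.csv"), stringsAsFactors = FALSE)
  counts$date <- as.Date(counts$date)
  tr <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  truth <- list(baseline_log_rate = unlist(tr$baseline_log_rate),
                stratum_effects = tr$stratum_effects,
                true_lag_log_rr = as.numeric(tr$true_lag_log_rr),
                true_lag_log_rr_resp = as.numeric(tr$true_lag_log_rr_resp),
                temp_effect_spec = tr$temp_effect_spec,
                config = man)
  class(truth) <- "sim_truth"
  out <- list(config = man,
              base = list(
                county_units = utils::read.csv(file.path(dir, "county_units.csv"),
                                               stringsAsFactors = FALSE),
                state_totals = utils::read.csv(file.path(dir, "state_totals.csv"),
                                               stringsAsFactors = FALSE)),
              series = hrs, weather = weather, counts = counts, truth = truth)
  cl <- file.path(dir, "claims.csv")
  if (file.exists(cl)) {
    out$claims <- utils::read.csv(cl, stringsAsFactors = FALSE)
    out$claims$date <- as.Date(out$claims$date)
  }
  out
}
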