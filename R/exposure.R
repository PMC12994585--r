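# County-day exposure construction from hourly customers-out feeds:
# customer-base estimation, missingness audit, gap imputation, run detection
# and continuous hours-without-power.

#' Exposure-definition parameters
#'
#' @param pct_threshold fraction of county customers that must be without
#'   power for an hour to count as "out" (default 0.01; secondary analyses
#'   use 0.03 and 0.05).
#' @param min_duration_hours minimum consecutive out-hours for a qualifying
#'   run (default 8; sensitivity values 4 and 12).
#' @param locf_max_gap_hours longest missing run filled by carrying the last
#'   observation forward (default 4).
#' @param county_missing_exclusion counties with a larger missing fraction of
#'   county-hours are excluded (default 0.50; sensitivity 0.20).
#' @param gap_fill_policy `"locf_then_zero"` (default): gaps up to
#'   `locf_max_gap_hours` are carried forward, longer gaps and leading
#'   missingness are set to zero (no outage); `"zero"`: every missing hour is
#'   set to zero.
#' @param run_day_attribution `"all_days"` (default): every calendar day
#'   touched by a qualifying run is exposed; `"start_day"`: only the day the
#'   run starts.
#' @return list of class `exposure_spec`.
#' @export
exposure_spec <- function(pct_threshold = 0.01,
                          min_duration_hours = 8L,
                          locf_max_gap_hours = 4L,
                          county_missing_exclusion = 0.50,
                          gap_fill_policy = c("locf_then_zero", "zero"),
                          run_day_attribution = c("all_days", "start_day")) {
  stopifnot(pct_threshold > 0, pct_threshold < 1, min_duration_hours >= 1)
  out <- list(pct_threshold = pct_threshold,
              min_duration_hours = as.integer(min_duration_hours),
              locf_max_gap_hours = as.integer(locf_max_gap_hours),
              county_missing_exclusion = county_missing_exclusion,
              gap_fill_policy = match.arg(gap_fill_policy),
              run_day_attribution = match.arg(run_day_attribution))
  class(out) <- "exposure_spec"
  out
}

#' Estimate county customer counts by proportional allocation
#'
#' Allocates each state's total customer count to its counties in proportion
#' to their household/establishment units:
#' `estimated = round(state_total * county_units / sum(county_units in state))`.
#'
#' @param county_units data.frame with county_id, state_id, county_units.
#' @param state_totals data.frame with state_id, total_customers.
#' @return the county table with an `estimated_customers` column (and the
#'   matched `total_customers`). Counties with zero units get estimate 0 and
#'   are flagged with a warning.
#' @export
estimate_customers <- function(county_units, state_totals) {
  m <- match(county_units$state_id, state_totals$state_id)
  if (anyNA(m)) {
    bad <- unique(county_units$state_id[is.na(m)])
    stop("state(s) without customer totals: ", paste(bad, collapse = ", "))
  }
  tot <- state_totals$total_customers[m]
  if (any(tot <= 0)) stop("state customer totals must be positive")
  ssum <- stats::ave(county_units$county_units, county_units$state_id, FUN = sum)
  est <- as.integer(round(as.numeric(tot) * county_units$county_units / ssum))
  out <- county_units
  out$total_customers <- tot
  out$estimated_customers <- est
  if (any(county_units$county_units == 0))
    warning(sum(county_units$county_units == 0),
            " county(ies) with zero units: customer estimate set to 0")
  out
}

# split a series data.frame into per-county integer vectors plus bookkeeping
split_series <- function(series) {
  stopifnot(all(c("county_id", "customers_out") %in% names(series)))
  idx <- split(seq_len(nrow(series)), series$county_id)
  lapply(idx, function(i) list(i = i, x = series$customers_out[i]))
}

#' Fraction of missing county-hours per county
#'
#' Computed on the raw feed, before any imputation.
#'
#' @param series hourly series data.frame (county_id, timestamp,
#'   customers_out with NA for missing).
#' @param window optional vector of two timestamps restricting the audit.
#' @return data.frame county_id, n_hours, n_missing, frac_missing.
#' @export
audit_missingness <- function(series, window = NULL) {
  if (!is.null(window)) {
    series <- series[series$timestamp >= window[1] & series$timestamp <= window[2], ,
                     drop = FALSE]
    if (nrow(series) == 0L) stop("audit window contains no hours")
  }
  n <- tapply(series$customers_out, series$county_id, length)
  miss <- tapply(is.na(series$customers_out), series$county_id, sum)
  data.frame(county_id = names(n), n_hours = as.integer(n),
             n_missing = as.integer(miss),
             frac_missing = as.numeric(miss) / as.numeric(n),
             stringsAsFactors = FALSE, row.names = NULL)
}

# fill one county's vector; returns list(x, imputed, zeroed)
fill_gaps_vec <- function(x, max_gap, policy) {
  if (!anyNA(x)) return(list(x = x, imputed = 0L, zeroed = 0L))
  r <- rle(is.na(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  imputed <- 0L; zeroed <- 0L
  for (k in which(r$values)) {
    s <- starts[k]; e <- ends[k]; len <- r$lengths[k]
    if (policy == "locf_then_zero" && s > 1L && len <= max_gap) {
      x[s:e] <- x[s - 1L]
      imputed <- imputed + len
    } else {
      x[s:e] <- 0L
      zeroed <- zeroed + len
    }
  }
  list(x = x, imputed = imputed, zeroed = zeroed)
}

#' Impute gaps in an hourly outage series
#'
#' Missing runs no longer than `spec$locf_max_gap_hours` are filled by
#' carrying the last preceding observation forward; longer runs and leading
#' missingness are set to 0 (treated as no outage). With
#' `gap_fill_policy = "zero"` every missing hour is set to 0. The output
#' contains no missing values.
#'
#' @param series hourly series data.frame.
#' @param spec an [exposure_spec()].
#' @return the series with gaps filled; per-county counts of imputed (LOCF)
#'   and zero-filled hours are attached as attribute `"fill_counts"`.
#' @export
impute_gaps <- function(series, spec = exposure_spec()) {
  parts <- split_series(series)
  x <- series$customers_out
  fills <- data.frame(county_id = names(parts),
                      imputed_hours = 0L, zeroed_hours = 0L,
                      stringsAsFactors = FALSE, row.names = NULL)
  for (j in seq_along(parts)) {
    p <- parts[[j]]
    f <- fill_gaps_vec(p$x, spec$locf_max_gap_hours, spec$gap_fill_policy)
    x[p$i] <- f$x
    fills$imputed_hours[j] <- f$imputed
    fills$zeroed_hours[j] <- f$zeroed
  }
  out <- series
  out$customers_out <- x
  attr(out, "fill_counts") <- fills
  attr(out, "origin") <- attr(series, "origin")
  out
}

# per-county logical "out" vector at a threshold; ratio clamped at 1
out_indicator <- function(x, est, pct) {
  if (any(x > est)) x <- pmin(x, est)   # clamp ratio at 1
  x / est >= pct
}

# mark exposed day indices (1-based within county) for one out-vector
runs_to_days <- function(o, min_dur, attribution) {
  r <- rle(o)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_dur)
  if (!length(keep)) return(integer(0))
  if (attribution == "start_day") {
    sort(unique((starts[keep] - 1L) %/% 24L + 1L))
  } else {
    days <- lapply(keep, function(k)
      ((starts[k] - 1L) %/% 24L):((ends[k] - 1L) %/% 24L) + 1L)
    sort(unique(unlist(days)))
  }
}

#' Detect exposed county-days from a gap-free hourly series
#'
#' An hour is "out" when `customers_out / estimated_customers >=
#' pct_threshold` (the ratio is clamped at 1 if the feed reports more
#' customers out than estimated). A maximal consecutive run of out-hours of
#' at least `min_duration_hours` marks every calendar day it touches as
#' exposed (or only its start day, per `spec$run_day_attribution`).
#'
#' @param series gap-free hourly series (run [impute_gaps()] first).
#' @param base customer table from [estimate_customers()].
#' @param spec an [exposure_spec()].
#' @return data.frame county_id, date of exposed county-days.
#' @export
detect_runs <- function(series, base, spec = exposure_spec()) {
  if (anyNA(series$customers_out))
    stop("series contains missing hours; run impute_gaps() first")
  origin <- series_origin(series)
  parts <- split_series(series)
  est <- base$estimated_customers[match(names(parts), base$county_id)]
  res <- vector("list", length(parts))
  clamped <- FALSE
  for (j in seq_along(parts)) {
    if (is.na(est[j]) || est[j] == 0L) {
      warning("county ", names(parts)[j],
              " skipped: no (positive) customer estimate")
      next
    }
    x <- parts[[j]]$x
    if (any(x > est[j])) clamped <- TRUE
    o <- out_indicator(x, est[j], spec$pct_threshold)
    d <- runs_to_days(o, spec$min_duration_hours, spec$run_day_attribution)
    if (length(d))
      res[[j]] <- data.frame(county_id = names(parts)[j],
                             date = origin + d - 1L,
                             stringsAsFactors = FALSE)
  }
  if (clamped)
    warning("customers_out exceeded the customer estimate for some hours; ",
            "ratio clamped at 1")
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(county_id = character(), date = as.Date(character()),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

series_origin <- function(series) {
  origin <- attr(series, "origin")
  if (is.null(origin)) origin <- as.Date(min(series$timestamp), tz = "UTC")
  origin
}

#' Daily hours without power
#'
#' Number of hours per county-day during which at least `pct` of customers
#' were without power (0-24).
#'
#' @param series gap-free hourly series.
#' @param base customer table from [estimate_customers()].
#' @param pct customer-fraction threshold (the continuous metric always uses
#'   1 percent).
#' @return data.frame county_id, date, hours_out.
#' @export
daily_hours_out <- function(series, base, pct = 0.01) {
  if (anyNA(series$customers_out))
    stop("series contains missing hours; run impute_gaps() first")
  origin <- series_origin(series)
  est <- base$estimated_customers[match(series$county_id, base$county_id)]
  out <- pmin(series$customers_out, est) / est >= pct
  day <- as.Date(series$timestamp, tz = "UTC")
  agg <- stats::aggregate(out, by = list(county_id = series$county_id, date = day),
                          FUN = sum)
  names(agg)[3] <- "hours_out"
  agg <- agg[order(agg$county_id, agg$date), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Retain counties below the missingness exclusion threshold
#'
#' @param audit output of [audit_missingness()].
#' @param spec an [exposure_spec()]; counties with
#'   `frac_missing > county_missing_exclusion` are excluded.
#' @return character vector of retained county ids, with the number excluded
#'   as attribute `"n_excluded"`.
#' @export
filter_counties <- function(audit, spec = exposure_spec()) {
  keep <- audit$frac_missing <= spec$county_missing_exclusion
  if (!any(keep)) stop("no counties retained at missingness cutoff ",
                       spec$county_missing_exclusion)
  out <- audit$county_id[keep]
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Full county-day exposure table
#'
#' Runs the exposure pipeline on a raw hourly feed: missingness audit, county
#' exclusion, gap imputation, run detection for every requested (duration,
#' threshold) pair, and the continuous daily hours-without-power metric
#' (always at the 1 percent threshold). Exposure flags are named
#' `exposed_<duration>h_p<threshold*100>`; the default main-analysis flag is
#' `exposed_8h_p1`.
#'
#' @param series raw hourly series (may contain missing hours).
#' @param base customer table from [estimate_customers()].
#' @param spec an [exposure_spec()].
#' @param durations run durations (hours) to flag.
#' @param thresholds customer-fraction thresholds to flag.
#' @return dense data.frame with one row per retained county-day: county_id,
#'   date, one logical column per (duration, threshold) pair, hours_out,
#'   imputed_hours and missing_hours (zero-filled hours) per county-day.
#'   Attributes: `"audit"`, `"retained"`, `"n_excluded"`.
#' @export
exposure_table <- function(series, base, spec = exposure_spec(),
                           durations = c(4L, 8L, 12L),
                           thresholds = c(0.01, 0.03, 0.05)) {
  audit <- audit_missingness(series)
  retained <- filter_counties(audit, spec)
  series <- series[series$county_id %in% retained, , drop = FALSE]
  origin <- series_origin(series)
  raw_na <- is.na(series$customers_out)
  imp <- impute_gaps(series, spec)
  # classify filled hours: restored by LOCF vs zero-filled
  filled_locf <- raw_na & imp$customers_out != 0L
  filled_zero <- raw_na & imp$customers_out == 0L

  parts <- split_series(imp)
  est <- base$estimated_customers[match(names(parts), base$county_id)]
  n_days <- vapply(parts, function(p) length(p$x) %/% 24L, integer(1))
  grid <- data.frame(
    county_id = rep(names(parts), times = n_days),
    date = origin + unlist(lapply(n_days, seq_len), use.names = FALSE) - 1L,
    stringsAsFactors = FALSE)
  grid_off <- c(0L, cumsum(n_days))            # rows of grid per county

  for (th in thresholds) for (du in sort(durations)) grid[[flag_name(du, th)]] <- FALSE
  grid$hours_out <- 0L

  for (j in seq_along(parts)) {
    if (is.na(est[j]) || est[j] == 0L) {
      warning("county ", names(parts)[j],
              " skipped: no (positive) customer estimate")
      next
    }
    x <- pmin(parts[[j]]$x, est[j])
    roff <- grid_off[j] + seq_len(n_days[j])
    for (th in thresholds) {
      o <- x / est[j] >= th
      for (du in durations) {
        d <- runs_to_days(o, as.integer(du), spec$run_day_attribution)
        if (length(d)) grid[[flag_name(du, th)]][roff[d]] <- TRUE
      }
      if (isTRUE(all.equal(th, 0.01))) {
        ho <- as.integer(rowsum(as.integer(o),
                                rep(seq_len(n_days[j]), each = 24L)))
        grid$hours_out[roff] <- ho
      }
    }
  }
  # per-day fill bookkeeping; hour -> county-day index follows grid's layout
  hour_within <- unlist(lapply(parts, function(p) seq_along(p$i)), use.names = FALSE)
  day_idx <- rep(grid_off[-length(grid_off)],
                 times = n_days * 24L) + (hour_within - 1L) %/% 24L + 1L
  ord <- unlist(lapply(parts, `[[`, "i"), use.names = FALSE)
  grid$imputed_hours <- as.integer(rowsum(as.integer(filled_locf[ord]), day_idx))
  grid$missing_hours <- as.integer(rowsum(as.integer(filled_zero[ord]), day_idx))
  attr(grid, "audit") <- audit
  attr(grid, "retained") <- as.character(retained)
  attr(grid, "n_excluded") <- attr(retained, "n_excluded")
  grid
}

flag_name <- function(duration, threshold) {
  pct <- threshold * 100
  pct_str <- if (pct == round(pct)) sprintf("%d", as.integer(pct)) else
    sub("0+$", "", sprintf("%g", pct))
  sprintf("exposed_%dh_p%s", as.integer(duration), pct_str)
}
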