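# Time-stratified case-crossover strata, analysis-row assembly, and
# climatology-based anomalous-day / smoke-day flags.

#' Time-stratified referent strata
#'
#' Each county-day belongs to exactly one stratum defined by county, year,
#' month and day of week, so its referent days are the other same-weekday
#' days of the same county-month (4-5 days per stratum).
#'
#' @param county_id character vector.
#' @param date Date vector, same length.
#' @return character stratum keys `"county|year|month|weekday"`.
#' @export
build_strata <- function(county_id, date) {
  date <- as.Date(date)
  paste(county_id, format(date, "%Y"), as.integer(format(date, "%m")),
        as.integer(format(date, "%u")), sep = "|")
}

#' Climatology thresholds for anomalous-day definitions
#'
#' @param hot_percentile,cold_percentile reference-period temperature
#'   percentiles (defaults 0.85 and 0.15).
#' @param hot_cutoff_c,cold_cutoff_c absolute cutoffs in degrees Celsius
#'   (defaults 24 and 0).
#' @param min_n minimum reference observations per county.
#' @return list of class `climatology_spec`.
#' @export
climatology_spec <- function(hot_percentile = 0.85, cold_percentile = 0.15,
                             hot_cutoff_c = 24, cold_cutoff_c = 0,
                             min_n = 100L) {
  stopifnot(cold_percentile < hot_percentile)
  out <- list(hot_percentile = hot_percentile, cold_percentile = cold_percentile,
              hot_cutoff_c = hot_cutoff_c, cold_cutoff_c = cold_cutoff_c,
              min_n = as.integer(min_n))
  class(out) <- "climatology_spec"
  out
}

#' Per-county reference temperature percentiles
#'
#' Empirical percentiles (linear interpolation between order statistics,
#' `stats::quantile` type 7; the convention is recorded in the output).
#' Counties with fewer than `spec$min_n` reference values are flagged and get
#' no percentiles.
#'
#' @param reference data.frame with county_id and tmax_c over the reference
#'   period.
#' @param spec a [climatology_spec()].
#' @return data.frame county_id, p_cold, p_hot, n, ok; attribute
#'   `"quantile_type"` records the interpolation convention.
#' @export
climatology_percentiles <- function(reference, spec = climatology_spec()) {
  sp <- split(reference$tmax_c, reference$county_id)
  n <- vapply(sp, length, integer(1))
  ok <- n >= spec$min_n
  p_cold <- p_hot <- rep(NA_real_, length(sp))
  p_cold[ok] <- vapply(sp[ok], stats::quantile, numeric(1),
                       probs = spec$cold_percentile, names = FALSE, type = 7)
  p_hot[ok] <- vapply(sp[ok], stats::quantile, numeric(1),
                      probs = spec$hot_percentile, names = FALSE, type = 7)
  if (any(!ok))
    warning(sum(!ok), " county(ies) with insufficient reference data; ",
            "no percentiles computed")
  out <- data.frame(county_id = names(sp), p_cold = p_cold, p_hot = p_hot,
                    n = n, ok = ok, stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "quantile_type") <- 7L
  out
}

#' Flag anomalously hot and cold days
#'
#' A day is anomalously hot when its maximal temperature strictly exceeds
#' both the county's hot reference percentile and the absolute cutoff
#' (default 24 C), and anomalously cold when strictly below both the cold
#' percentile and the cold cutoff (default 0 C). The two flags are mutually
#' exclusive whenever the hot cutoff exceeds the cold cutoff.
#'
#' @param weather data.frame with county_id, date, tmax_c.
#' @param percentiles output of [climatology_percentiles()].
#' @param spec a [climatology_spec()].
#' @return the weather table with logical hot_day and cold_day columns;
#'   counties lacking percentiles get FALSE flags and are listed in the
#'   `"no_climatology"` attribute.
#' @export
flag_anomalous <- function(weather, percentiles, spec = climatology_spec()) {
  m <- match(weather$county_id, percentiles$county_id)
  p_hot <- percentiles$p_hot[m]
  p_cold <- percentiles$p_cold[m]
  hot <- weather$tmax_c > p_hot & weather$tmax_c > spec$hot_cutoff_c
  cold <- weather$tmax_c < p_cold & weather$tmax_c < spec$cold_cutoff_c
  hot[is.na(hot)] <- FALSE
  cold[is.na(cold)] <- FALSE
  out <- weather
  out$hot_day <- hot
  out$cold_day <- cold
  missing_counties <- unique(weather$county_id[is.na(m) |
                                                 !percentiles$ok[pmax(m, 1L)]])
  attr(out, "no_climatology") <- missing_counties[!is.na(missing_counties)]
  out
}

#' Flag wildfire smoke days
#'
#' A county-day is a smoke day when the wildfire PM2.5 concentration is
#' strictly positive. Missing concentrations become FALSE with a warning;
#' negative concentrations are an error.
#'
#' @param weather data.frame with a smoke_ugm3 column.
#' @return weather with a logical smoke_day column.
#' @export
flag_smoke <- function(weather) {
  s <- weather$smoke_ugm3
  if (any(s < 0, na.rm = TRUE)) stop("negative smoke concentration")
  if (anyNA(s)) {
    warning(sum(is.na(s)), " missing smoke concentration(s) treated as no smoke")
    s[is.na(s)] <- 0
  }
  out <- weather
  out$smoke_day <- s > 0
  out
}

#' Assemble case-crossover analysis rows
#'
#' Joins daily outcome counts, county-day exposure and weather into one row
#' per county-day with complete 7-day exposure and temperature lag histories
#' (lag 0 = same day). Days whose 6-day lookback precedes the county's data
#' start are dropped, as are strata with zero outcome total (they contribute
#' nothing to the conditional Poisson likelihood) and strata with fewer than
#' two remaining days.
#'
#' @param counts data.frame county_id, date, cvd_count, resp_count (or a `y`
#'   column selected via `outcome = "y"`).
#' @param exposure county-day table from [exposure_table()] (or any table
#'   with county_id, date and the chosen exposure column).
#' @param weather data.frame county_id, date, tmax_c, precip_mm, wind_ms, and
#'   optionally hot_day/cold_day ([flag_anomalous()]) and smoke_day
#'   ([flag_smoke()]).
#' @param outcome `"cvd"`, `"resp"` or the name of a count column.
#' @param exposure_col exposure column used for the lag history, e.g.
#'   `"exposed_8h_p1"` (binary) or `"hours_out"` (continuous).
#' @param n_lags number of lags including lag 0 (fixed design: 7).
#' @return data.frame with county_id, date, stratum, y, exp_l0..exp_l6,
#'   tmax_l0..tmax_l6, precip_mm, wind_ms, hot_day, cold_day, smoke_day.
#'   Attributes record dropped-row bookkeeping.
#' @export
assemble_rows <- function(counts, exposure, weather,
                          outcome = c("cvd", "resp"),
                          exposure_col = "exposed_8h_p1",
                          n_lags = 7L) {
  outcome <- if (outcome[1] %in% c("cvd", "resp")) match.arg(outcome) else outcome[1]
  ycol <- switch(outcome, cvd = "cvd_count", resp = "resp_count", outcome)
  if (!ycol %in% names(counts)) stop("no outcome column ", ycol, " in counts")
  if (!exposure_col %in% names(exposure))
    stop("no exposure column ", exposure_col, " in exposure table")

  key_c <- key_county_date(counts$county_id, counts$date)
  key_e <- key_county_date(exposure$county_id, exposure$date)
  key_w <- key_county_date(weather$county_id, weather$date)
  # analysis set = counties retained in the exposure table
  me <- match(key_e, key_c)
  mw <- match(key_e, key_w)
  if (anyNA(me))
    stop("counts missing for county-day ", key_e[which(is.na(me))[1]])
  if (anyNA(mw))
    stop("weather missing for county-day ", key_e[which(is.na(mw))[1]])

  df <- data.frame(county_id = exposure$county_id,
                   date = as.Date(exposure$date),
                   y = counts[[ycol]][me],
                   expv = as.numeric(exposure[[exposure_col]]),
                   tmax = weather$tmax_c[mw],
                   precip_mm = weather$precip_mm[mw],
                   wind_ms = weather$wind_ms[mw],
                   hot_day = if ("hot_day" %in% names(weather))
                     weather$hot_day[mw] else FALSE,
                   cold_day = if ("cold_day" %in% names(weather))
                     weather$cold_day[mw] else FALSE,
                   smoke_day = if ("smoke_day" %in% names(weather))
                     weather$smoke_day[mw] else FALSE,
                   stringsAsFactors = FALSE)
  df <- df[order(df$county_id, df$date), , drop = FALSE]

  # per-county contiguity check and lag-history construction
  sp <- split(seq_len(nrow(df)), df$county_id)
  keep_rows <- integer(0)
  EX <- TM <- NULL
  ex_list <- tm_list <- vector("list", length(sp))
  for (j in seq_along(sp)) {
    i <- sp[[j]]
    d <- df$date[i]
    if (length(i) >= 2L && any(diff(as.integer(d)) != 1L))
      stop("non-contiguous dates for county ", df$county_id[i[1]],
           " at ", d[which(diff(as.integer(d)) != 1L)[1] + 1L])
    if (length(i) < n_lags) next
    ex_list[[j]] <- stats::embed(df$expv[i], n_lags)   # cols: lag0..lag6
    tm_list[[j]] <- stats::embed(df$tmax[i], n_lags)
    keep_rows <- c(keep_rows, i[n_lags:length(i)])
  }
  EX <- do.call(rbind, ex_list)
  TM <- do.call(rbind, tm_list)
  n_lookback_dropped <- nrow(df) - length(keep_rows)
  out <- df[keep_rows, c("county_id", "date", "y", "precip_mm", "wind_ms",
                         "hot_day", "cold_day", "smoke_day")]
  colnames(EX) <- paste0("exp_l", 0:(n_lags - 1L))
  colnames(TM) <- paste0("tmax_l", 0:(n_lags - 1L))
  out <- cbind(out, EX, TM)
  out$stratum <- build_strata(out$county_id, out$date)

  # strata with zero outcome total are uninformative; so are singleton strata
  tot <- tapply(out$y, out$stratum, sum)
  zero_strata <- names(tot)[tot == 0]
  out2 <- out[!(out$stratum %in% zero_strata), , drop = FALSE]
  sz <- table(out2$stratum)
  small <- names(sz)[sz < 2L]
  out3 <- out2[!(out2$stratum %in% small), , drop = FALSE]
  rownames(out3) <- NULL
  attr(out3, "outcome") <- outcome
  attr(out3, "exposure_col") <- exposure_col
  attr(out3, "n_dropped_lookback") <- n_lookback_dropped
  attr(out3, "n_dropped_zero_strata") <- nrow(out) - nrow(out2)
  attr(out3, "n_dropped_small_strata") <- nrow(out2) - nrow(out3)
  out3
}
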