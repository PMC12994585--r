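# Claim classification and county-day outcome tabulation.

# qualifying prefixes: ICD-10 chapter I (circulatory) and J (respiratory),
# judged on the first five diagnosis positions of non-planned admissions.
code_is_cvd <- function(code) grepl("^I[0-9]{2}", code)
code_is_resp <- function(code) grepl("^J[0-9]{2}", code)

clean_codes <- function(codes) toupper(gsub("[^A-Za-z0-9]", "", codes))

#' Classify claims into outcome groups
#'
#' A planned admission is never counted. Otherwise a claim counts as CVD if
#' any of its first five diagnosis codes starts with I00-I99, as respiratory
#' if any starts with J00-J99, as BOTH if both, and NONE otherwise. Codes are
#' upper-cased and stripped of punctuation before matching; codes that do not
#' look like ICD-10 (letter followed by digits) are ignored with one warning.
#'
#' @param claims data.frame with admission_type and dx1..dx10 (at least dx1).
#' @return character vector in {"CVD","RESP","BOTH","NONE"}, one per claim.
#' @export
classify_claims <- function(claims) {
  n <- nrow(claims)
  dx_cols <- intersect(paste0("dx", 1:5), names(claims))
  if (!length(dx_cols)) stop("claims must contain dx1..dx5 columns")
  is_cvd <- logical(n); is_resp <- logical(n); malformed <- 0L
  for (col in dx_cols) {
    code <- clean_codes(claims[[col]])
    bad <- !is.na(code) & code != "" & !grepl("^[A-Z][0-9]", code)
    malformed <- malformed + sum(bad)
    code[bad] <- ""
    is_cvd <- is_cvd | code_is_cvd(code)
    is_resp <- is_resp | code_is_resp(code)
  }
  if (malformed > 0L)
    warning(malformed, " malformed diagnosis code(s) ignored")
  out <- rep("NONE", n)
  out[is_cvd] <- "CVD"
  out[is_resp] <- "RESP"
  out[is_cvd & is_resp] <- "BOTH"
  out[claims$admission_type == "planned"] <- "NONE"
  out
}

#' Classify a single claim record
#'
#' @param admission_type one of "emergency", "urgent", "planned".
#' @param dx_codes ordered character vector of diagnosis codes.
#' @return "CVD", "RESP", "BOTH" or "NONE".
#' @export
classify_claim <- function(admission_type, dx_codes) {
  stopifnot(length(dx_codes) >= 1)
  df <- data.frame(admission_type = admission_type, stringsAsFactors = FALSE)
  for (j in 1:10) df[[paste0("dx", j)]] <-
    if (j <= length(dx_codes)) dx_codes[j] else ""
  classify_claims(df)
}

#' Tabulate claims into a dense county-day outcome grid
#'
#' Zeroes are included for every county-day in the window. Claims classified
#' BOTH increment both outcome counts; claims dated outside the window are
#' dropped (their number is attached as attribute `"n_dropped"`).
#'
#' @param claims claims data.frame (county_id, date, admission_type, dx*).
#' @param window Date vector of length 2 (inclusive range) or the full vector
#'   of study days.
#' @param county_ids counties to tabulate; defaults to those in the claims.
#' @return data.frame county_id, date, cvd_count, resp_count, dense over
#'   counties x days.
#' @export
tabulate_claims <- function(claims, window, county_ids = NULL) {
  window <- as.Date(window)
  days <- if (length(window) == 2L) seq(window[1], window[2], by = "day") else
    sort(unique(window))
  if (is.null(county_ids)) county_ids <- sort(unique(claims$county_id))
  cls <- classify_claims(claims)
  dt <- as.Date(claims$date)
  inside <- dt >= min(days) & dt <= max(days)
  n_drop <- sum(!inside)
  if (n_drop) message(n_drop, " claim(s) outside the study window dropped")
  grid <- data.frame(
    county_id = rep(county_ids, times = length(days)),
    date = rep(days, each = length(county_ids)),
    stringsAsFactors = FALSE)
  key <- key_county_date(grid$county_id, grid$date)
  ckey <- key_county_date(claims$county_id, dt)
  add <- function(sel) {
    t0 <- table(factor(ckey[sel & inside], levels = key))
    as.integer(t0)
  }
  grid$cvd_count <- add(cls %in% c("CVD", "BOTH"))
  grid$resp_count <- add(cls %in% c("RESP", "BOTH"))
  grid <- grid[order(grid$county_id, grid$date), , drop = FALSE]
  rownames(grid) <- NULL
  attr(grid, "n_dropped") <- n_drop
  attr(grid, "n_both") <- sum(cls == "BOTH")
  grid
}
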