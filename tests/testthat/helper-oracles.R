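# Independent re-implementations used as test oracles. Each is written in
# the most transparent way possible (explicit loops, stats::glm) so that the
# production code is checked against a different algorithm, not itself.

# Brute-force exposed-day oracle: scan every maximal run of consecutive
# out-hours by explicit loop and mark the days it touches.
oracle_exposed_days <- function(out_hours, min_dur) {
  n <- length(out_hours)
  days <- integer(0)
  i <- 1L
  while (i <= n) {
    if (out_hours[i]) {
      j <- i
      while (j < n && out_hours[j + 1L]) j <- j + 1L
      if (j - i + 1L >= min_dur)
        days <- c(days, ((i - 1L) %/% 24L):((j - 1L) %/% 24L) + 1L)
      i <- j + 1L
    } else i <- i + 1L
  }
  sort(unique(days))
}

# Stratum-dummy Poisson GLM oracle: the conditional fit must agree with
# maximum-likelihood Poisson regression carrying one intercept per stratum.
oracle_glm_fit <- function(y, X, strata) {
  g <- factor(strata)
  tot <- tapply(y, g, sum)
  sz <- table(g)
  keep <- g %in% names(tot)[tot > 0 & sz >= 2]
  d <- data.frame(y = y[keep])
  Xk <- X[keep, , drop = FALSE]
  gk <- droplevels(g[keep])
  fit <- stats::glm(y ~ Xk + gk, family = stats::poisson(), data = d,
                    control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  co <- stats::coef(fit)
  idx <- grep("^Xk", names(co))
  V <- stats::vcov(fit)[idx, idx, drop = FALSE]
  list(coef = unname(co[idx]), vcov = unname(V))
}

# Small random conditional-Poisson datasets with a known shape.
random_small_dataset <- function(n_strata = 25L, k = 3L, stratum_size = 4L) {
  n <- n_strata * stratum_size
  strata <- rep(seq_len(n_strata), each = stratum_size)
  X <- matrix(stats::rnorm(n * k), n, k)
  beta <- stats::rnorm(k, sd = 0.3)
  alpha <- stats::runif(n_strata, log(2), log(8))
  mu <- exp(alpha[strata] + as.vector(X %*% beta))
  y <- stats::rpois(n, mu)
  list(y = y, X = X, strata = strata, beta = beta)
}

# A random hourly series (one county, whole days) mixing zeros, short and
# long out-runs; returns the series values plus the out-hour indicator that
# a given estimate/threshold implies.
random_hourly_series <- function(n_days, est = 1000L, pct = 0.01) {
  n <- n_days * 24L
  x <- integer(n)
  n_runs <- stats::rpois(1, 3)
  if (n_runs > 0) for (r in seq_len(n_runs)) {
    start <- sample.int(n, 1)
    len <- sample.int(30L, 1)
    stop_at <- min(n, start + len - 1L)
    lvl <- sample(c(est %/% 200L, est %/% 50L, est %/% 2L), 1)
    x[start:stop_at] <- lvl
  }
  x
}

# Quick small study bundle shared by several tests (built once per test run).
tiny_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_study(fixture_config("tiny"))
    cache
  }
})

# Full county x day matrix of the continuous hours metric from an exposure
# table, aligned to a config's grid (zero where a county was excluded).
hours_matrix <- function(et, config) {
  dates <- config$start_date + seq_len(config$n_days) - 1L
  cid <- sprintf("C%04d", seq_len(config$n_counties))
  M <- matrix(0, config$n_counties, config$n_days,
              dimnames = list(cid, as.character(dates)))
  M[cbind(match(et$county_id, cid),
          match(as.character(et$date), as.character(dates)))] <- et$hours_out
  M
}

# Pooled lag-1 autocorrelation of a 0/1 series split by county.
pooled_lag1_autocorr <- function(x, county) {
  mu <- mean(x)
  num <- 0; den <- 0
  for (v in split(x, county)) {
    n <- length(v)
    num <- num + sum((v[-1] - mu) * (v[-n] - mu))
    den <- den + sum((v - mu)^2)
  }
  num / den
}
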