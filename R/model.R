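# The user-facing model: design construction from assembled rows and the
# central case-crossover fitting function.

default_lag_df <- function(outcome, exposure) {
  # main-analysis defaults: lag-basis df 5 for CVD and 3 for respiratory
  # (binary exposure); 4 for the continuous hours metric
  if (exposure == "hours") 4L else if (outcome == "cvd") 5L else 3L
}

default_precip <- function(outcome) if (outcome == "cvd") "ns2" else "linear"

#' Build the case-crossover design matrix
#'
#' Assembles the full covariate design from analysis rows: the exposure
#' cross-basis (binary indicator or continuous hours, lag-constrained),
#' the temperature cross-basis (natural spline with 3 df on the var
#' dimension, spline-constrained lags 0-6), same-day precipitation (linear
#' for respiratory models, 2-df spline for CVD), same-day wind speed (3-df
#' spline), and optional smoke-day and anomalous-day interaction terms.
#'
#' @param rows output of [assemble_rows()].
#' @param outcome `"cvd"` or `"resp"` (defaults to the rows' outcome).
#' @param exposure `"binary"` or `"hours"`.
#' @param exposure_fun `"linear"` (identity; always used for binary) or
#'   `"ns"` with `exposure_df` columns, for the continuous metric.
#' @param exposure_df var-dimension df for `exposure_fun = "ns"`.
#' @param lag_df exposure lag-basis df (default: 5 CVD / 3 respiratory for
#'   the binary indicator, 4 for hours).
#' @param temp_df,temp_lag_df temperature var / lag basis df.
#' @param precip `"linear"` or `"ns2"`.
#' @param wind_df wind spline df.
#' @param smoke include the binary smoke-day adjustment column.
#' @return list: y, X, strata, exposure metadata and column index, block map.
#' @export
build_design <- function(rows,
                         outcome = attr(rows, "outcome"),
                         exposure = c("binary", "hours"),
                         exposure_fun = c("linear", "ns"),
                         exposure_df = 3L,
                         lag_df = NULL,
                         temp_df = 3L, temp_lag_df = 3L,
                         precip = NULL, wind_df = 3L,
                         smoke = FALSE) {
  exposure <- match.arg(exposure)
  exposure_fun <- if (exposure == "binary") "linear" else match.arg(exposure_fun)
  if (is.null(outcome)) stop("outcome not given and not recorded on rows")
  if (!outcome %in% c("cvd", "resp"))
    outcome <- if (grepl("resp", outcome)) "resp" else "cvd"
  if (is.null(lag_df)) lag_df <- default_lag_df(outcome, exposure)
  if (is.null(precip)) precip <- default_precip(outcome)

  EX <- as.matrix(rows[, paste0("exp_l", 0:6)])
  TM <- as.matrix(rows[, paste0("tmax_l", 0:6)])

  cb_exp <- cross_basis(EX,
                        var_kind = if (exposure_fun == "ns") "ns" else "linear",
                        var_df = exposure_df, lag_df = lag_df)
  colnames(cb_exp$X) <- paste0("exp_", colnames(cb_exp$X))
  cb_tmp <- cross_basis(TM, var_kind = "ns", var_df = temp_df,
                        lag_df = temp_lag_df)
  colnames(cb_tmp$X) <- paste0("tmax_", colnames(cb_tmp$X))

  Xp <- if (precip == "linear") {
    matrix(rows$precip_mm, ncol = 1, dimnames = list(NULL, "precip"))
  } else {
    B <- natural_spline_basis(rows$precip_mm, df = 2L)
    colnames(B) <- paste0("precip_ns", seq_len(ncol(B)))
    B
  }
  Xw <- natural_spline_basis(rows$wind_ms, df = wind_df)
  colnames(Xw) <- paste0("wind_ns", seq_len(ncol(Xw)))

  X <- cbind(cb_exp$X, cb_tmp$X, Xp, Xw)
  blocks <- list(exposure = seq_len(ncol(cb_exp$X)),
                 temperature = ncol(cb_exp$X) + seq_len(ncol(cb_tmp$X)),
                 precip = ncol(cb_exp$X) + ncol(cb_tmp$X) + seq_len(ncol(Xp)),
                 wind = ncol(cb_exp$X) + ncol(cb_tmp$X) + ncol(Xp) +
                   seq_len(ncol(Xw)))
  if (smoke) {
    X <- cbind(X, smoke_day = as.numeric(rows$smoke_day))
    blocks$smoke <- ncol(X)
  }
  list(y = rows$y, X = X, strata = rows$stratum,
       exposure_meta = cb_exp$meta, blocks = blocks,
       config = list(outcome = outcome, exposure = exposure,
                     exposure_fun = exposure_fun, exposure_df = exposure_df,
                     lag_df = lag_df, temp_df = temp_df,
                     temp_lag_df = temp_lag_df, precip = precip,
                     wind_df = wind_df, smoke = smoke))
}

# drop covariate (non-exposure) columns that are degenerate under the
# conditional likelihood: no within-stratum variation (e.g. an all-FALSE
# smoke indicator) or linearly dependent on the other columns after
# within-stratum centering (e.g. a sparse precipitation spline in small
# data); either makes the information matrix singular
screen_columns <- function(des) {
  X <- des$X
  g <- as.integer(factor(des$strata))
  n_g <- tabulate(g)
  M <- rowsum(X, g)
  ss <- colSums(X^2) - colSums(M^2 / n_g)
  ss_exp <- ss[des$blocks$exposure]
  if (any(ss_exp < 1e-10))
    stop("exposure block has no within-stratum variation; the conditional ",
         "likelihood cannot identify the exposure effect")
  dead <- setdiff(which(ss < 1e-10), des$blocks$exposure)

  # rank of the within-stratum-centered design, exposure columns pivoted
  # first so dependencies are resolved against covariate columns
  Xc <- X - (M / n_g)[g, , drop = FALSE]
  alive <- setdiff(seq_len(ncol(X)), dead)
  ord <- c(intersect(des$blocks$exposure, alive),
           setdiff(alive, des$blocks$exposure))
  qr_c <- qr(Xc[, ord, drop = FALSE])
  if (qr_c$rank < length(ord)) {
    dep <- ord[qr_c$pivot[(qr_c$rank + 1L):length(ord)]]
    if (any(dep %in% des$blocks$exposure))
      stop("exposure block is collinear within strata; the conditional ",
           "likelihood cannot identify the exposure effect")
    dead <- union(dead, dep)
  }

  if (length(dead)) {
    dead <- sort(dead)
    des$dropped_columns <- colnames(X)[dead]
    keepc <- setdiff(seq_len(ncol(X)), dead)
    remap <- match(seq_len(ncol(X)), keepc)
    des$X <- X[, keepc, drop = FALSE]
    des$blocks <- lapply(des$blocks, function(ix) {
      ix <- remap[ix]; ix[!is.na(ix)]
    })
  }
  des
}

#' Fit the time-stratified case-crossover model
#'
#' The central fitting function: builds the design from assembled
#' case-crossover rows ([assemble_rows()]) and maximizes the stratum-
#' conditioned Poisson likelihood ([fit_conditional_poisson()]). The result
#' carries the cross-basis metadata, so lag-specific and cumulative rate
#' ratios are available via [lag_rr()], [cumulative_rr()],
#' [exposure_response()] and the `predict`/`plot` methods.
#'
#' @inheritParams build_design
#' @param ... passed to [fit_conditional_poisson()] (`tol`, `maxit`).
#' @return object of class `c("cco_fit", "cpfit")`.
#' @export
#' @examples
#' cfg <- fixture_config("tiny")
#' sim <- simulate_study(cfg)
#' rows <- sim_rows(sim, outcome = "cvd")
#' fit <- cco_fit(rows)
#' fit
#' lag_rr(fit)
cco_fit <- function(rows, outcome = attr(rows, "outcome"),
                    exposure = c("binary", "hours"),
                    exposure_fun = c("linear", "ns"), exposure_df = 3L,
                    lag_df = NULL, temp_df = 3L, temp_lag_df = 3L,
                    precip = NULL, wind_df = 3L, smoke = FALSE, ...) {
  cl <- match.call()
  des <- build_design(rows, outcome = outcome, exposure = exposure,
                      exposure_fun = exposure_fun, exposure_df = exposure_df,
                      lag_df = lag_df, temp_df = temp_df,
                      temp_lag_df = temp_lag_df, precip = precip,
                      wind_df = wind_df, smoke = smoke)
  des <- screen_columns(des)
  fit <- fit_conditional_poisson(des$y, des$X, des$strata, ...)
  fit$call <- cl
  fit$exposure_meta <- des$exposure_meta
  fit$blocks <- des$blocks
  fit$model_config <- des$config
  fit$dropped_columns <- des$dropped_columns
  class(fit) <- c("cco_fit", "cpfit")
  fit
}

#' @export
print.cco_fit <- function(x, ...) {
  cfg <- x$model_config
  cat("Case-crossover conditional Poisson fit\n")
  cat(sprintf("  outcome: %s   exposure: %s (%s, lag df %d)\n",
              cfg$outcome, cfg$exposure, cfg$exposure_fun, cfg$lag_df))
  cat(sprintf("  %d rows in %d strata, %d parameters; converged: %s\n",
              x$n_obs, x$n_strata, x$k, x$converged))
  cat(sprintf("  conditional log-likelihood %.2f, qAIC (c=1) %.2f\n",
              x$loglik, qaic(x)))
  rr <- lag_rr(x)
  cat("  lag rate ratios (contrast 1 vs 0):\n")
  print(round(as.data.frame(rr)[, c("lag", "rr", "lo", "hi")], 4))
  invisible(x)
}

#' @export
summary.cco_fit <- function(object, level = 0.95, ...) {
  se <- sqrt(diag(object$vcov))
  z <- object$coefficients / se
  ct <- cbind(Estimate = object$coefficients, `Std. Error` = se,
              `z value` = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(coefficients = ct, dispersion = dispersion(object),
              qaic = qaic(object), lag_rr = lag_rr(object, level = level),
              cumulative = cumulative_rr(object, level = level),
              model_config = object$model_config,
              n_obs = object$n_obs, n_strata = object$n_strata,
              converged = object$converged)
  class(out) <- "summary.cco_fit"
  out
}

#' @export
print.summary.cco_fit <- function(x, ...) {
  cat("Case-crossover conditional Poisson model (", x$model_config$outcome,
      ", ", x$model_config$exposure, " exposure)\n", sep = "")
  cat(sprintf("%d rows in %d strata; dispersion %.3f; qAIC %.2f\n\n",
              x$n_obs, x$n_strata, x$dispersion, x$qaic))
  stats::printCoefmat(x$coefficients, signif.stars = FALSE)
  cat("\nLag rate ratios:\n")
  print(round(as.data.frame(x$lag_rr)[, c("lag", "rr", "lo", "hi")], 4))
  cum <- x$cumulative
  cat(sprintf("Cumulative (lags 0-6): RR %.4f (%.4f, %.4f)\n",
              cum$rr, cum$lo, cum$hi))
  invisible(x)
}

#' @export
predict.cco_fit <- function(object,
                            type = c("lag_rr", "cumulative", "exposure_response"),
                            ...) {
  type <- match.arg(type)
  switch(type,
         lag_rr = lag_rr(object, ...),
         cumulative = cumulative_rr(object, ...),
         exposure_response = exposure_response(object, ...))
}

#' Plot the lag rate-ratio curve of a fitted model
#'
#' @param x a [cco_fit()] object.
#' @param level confidence level.
#' @param ... further graphical parameters passed to `plot`.
#' @export
plot.cco_fit <- function(x, level = 0.95, ...) {
  rr <- lag_rr(x, level = level)
  df <- as.data.frame(rr)
  plot(df$lag, df$rr, ylim = range(df$lo, df$hi, 1), pch = 16,
       xlab = "lag (days)", ylab = "rate ratio", ...)
  graphics::segments(df$lag, df$lo, df$lag, df$hi)
  graphics::abline(h = 1, lty = 2)
  invisible(rr)
}
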