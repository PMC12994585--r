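# Config-driven orchestration of the pipeline stages, with JSON-lines
# logging, plus convenience wrappers used throughout the examples and tests.

#' Analysis rows straight from a study bundle
#'
#' Convenience wrapper: customer-base estimation, exposure table, smoke
#' flags and row assembly in one call.
#'
#' @param sim a bundle from [simulate_study()] or [read_fixture()].
#' @param outcome `"cvd"` or `"resp"`.
#' @param exposure_col exposure column for the lag history.
#' @param spec an [exposure_spec()].
#' @param climatology optional percentiles table for anomalous-day flags.
#' @return assembled rows (see [assemble_rows()]).
#' @export
sim_rows <- function(sim, outcome = "cvd", exposure_col = "exposed_8h_p1",
                     spec = exposure_spec(), climatology = NULL) {
  base <- estimate_customers(sim$base$county_units, sim$base$state_totals)
  et <- exposure_table(sim$series, base, spec)
  weather <- flag_smoke(sim$weather)
  if (!is.null(climatology))
    weather <- flag_anomalous(weather, climatology)
  assemble_rows(sim$counts, et, weather, outcome = outcome,
                exposure_col = exposure_col)
}

#' Split daily counts into outcome subgroups
#'
#' Thins each county-day count into named subgroups by multinomial
#' allocation, preserving the total — a simple way to emulate subgroup
#' outcome series (by sex, age band, ...) that share the same underlying
#' rate process.
#'
#' @param counts daily counts table.
#' @param props named numeric vector of subgroup proportions (summing to 1).
#' @param outcome `"cvd"` or `"resp"`.
#' @param seed RNG seed.
#' @return named list of counts tables, one per subgroup (the chosen outcome
#'   column is replaced; the other is zeroed).
#' @export
split_counts <- function(counts, props, outcome = "cvd", seed = 1L) {
  stopifnot(abs(sum(props) - 1) < 1e-8, !is.null(names(props)))
  ycol <- paste0(outcome, "_count")
  with_seed(seed, {
    y <- counts[[ycol]]
    alloc <- matrix(0L, length(y), length(props))
    # vectorized multinomial thinning via successive binomials
    rem <- y
    p_rem <- 1
    for (j in seq_along(props)) {
      if (j < length(props)) {
        pj <- props[j] / p_rem
        alloc[, j] <- stats::rbinom(length(rem), rem, pj)
        rem <- rem - alloc[, j]
        p_rem <- p_rem - props[j]
      } else alloc[, j] <- rem
    }
    out <- lapply(seq_along(props), function(j) {
      d <- counts
      d[[ycol]] <- alloc[, j]
      d
    })
    names(out) <- names(props)
    out
  })
}

log_line <- function(con, stage, ...) {
  rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage = stage),
           list(...))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(config, f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline from one configuration
#'
#' Stages: `simulate` (write a fixture bundle), `exposure` (customer
#' estimation, missingness audit, exposure table), `assemble` (analysis
#' rows), `fit` (main fit plus threshold/duration variants per toggles) and
#' `report` (lag-RR tables, qAIC tables, attributable counts). Every stage
#' writes delimited tables under `outdir` and appends to a JSON-lines log
#' recording the config hash, seed and row counts.
#'
#' @param config a list (or path to a YAML file) with components `sim`
#'   (arguments to [sim_config()] or a fixture name), `exposure` (arguments
#'   to [exposure_spec()]), `outcomes` (subset of c("cvd","resp")), and
#'   logical toggles `secondary_thresholds`, `durations`, `hours_model`,
#'   `attributable`.
#' @param outdir output directory.
#' @param stages which stages to run (in order).
#' @param overwrite allow reuse of an existing output directory.
#' @return (invisibly) a list with the fitted models and report tables.
#' @export
run_pipeline <- function(config, outdir,
                         stages = c("simulate", "exposure", "assemble",
                                    "fit", "report"),
                         overwrite = FALSE) {
  if (is.character(config) && length(config) == 1L && file.exists(config))
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(outdir, "pipeline_log.jsonl")
  con <- file(logf, open = "a")
  on.exit(close(con))
  hash <- config_hash(config)
  scfg <- if (is.character(config$sim)) fixture_config(config$sim) else
    do.call(sim_config, config$sim %||% list())
  espec <- do.call(exposure_spec, config$exposure %||% list())
  outcomes <- config$outcomes %||% c("cvd", "resp")
  log_line(con, "start", config_hash = hash, seed = scfg$seed)

  fixdir <- file.path(outdir, "fixture")
  if ("simulate" %in% stages) {
    make_fixture(scfg, fixdir, overwrite = overwrite,
                 claims = isTRUE(config$claims))
    log_line(con, "simulate", dir = fixdir)
  }
  if (!dir.exists(fixdir))
    stop("no fixture found; run the 'simulate' stage first")
  sim <- read_fixture(fixdir)

  results <- list()
  if (any(c("exposure", "assemble", "fit", "report") %in% stages)) {
    base <- estimate_customers(sim$base$county_units, sim$base$state_totals)
    et <- exposure_table(sim$series, base, espec)
    if ("exposure" %in% stages) {
      utils::write.csv(et, file.path(outdir, "exposure.csv"), row.names = FALSE)
      utils::write.csv(attr(et, "audit"), file.path(outdir, "missingness_audit.csv"),
                       row.names = FALSE)
      log_line(con, "exposure", n_rows = nrow(et),
               n_excluded = attr(et, "n_excluded"))
    }
    weather <- flag_smoke(sim$weather)
    rows <- lapply(outcomes, function(oc)
      assemble_rows(sim$counts, et, weather, outcome = oc))
    names(rows) <- outcomes
    if ("assemble" %in% stages) {
      for (oc in outcomes) {
        utils::write.csv(rows[[oc]],
                         file.path(outdir, paste0("rows_", oc, ".csv")),
                         row.names = FALSE)
        log_line(con, "assemble", outcome = oc, n_rows = nrow(rows[[oc]]),
                 n_dropped_lookback = attr(rows[[oc]], "n_dropped_lookback"),
                 n_dropped_zero_strata = attr(rows[[oc]], "n_dropped_zero_strata"))
      }
    }
    if (any(c("fit", "report") %in% stages)) {
      for (oc in outcomes) {
        fit <- cco_fit(rows[[oc]])
        results[[oc]]$fit <- fit
        results[[oc]]$lag_rr <- lag_rr(fit)
        variants <- list()
        if (isTRUE(config$secondary_thresholds)) {
          for (col in c("exposed_8h_p3", "exposed_8h_p5")) {
            r2 <- assemble_rows(sim$counts, et, weather, outcome = oc,
                                exposure_col = col)
            variants[[col]] <- lag_rr(cco_fit(r2))
          }
        }
        if (isTRUE(config$durations)) {
          for (col in c("exposed_4h_p1", "exposed_12h_p1")) {
            r2 <- assemble_rows(sim$counts, et, weather, outcome = oc,
                                exposure_col = col)
            variants[[col]] <- lag_rr(cco_fit(r2))
          }
        }
        results[[oc]]$variants <- variants
        if (isTRUE(config$hours_model)) {
          rh <- assemble_rows(sim$counts, et, weather, outcome = oc,
                              exposure_col = "hours_out")
          results[[oc]]$threshold_test <- run_threshold_test(rh)
        }
        log_line(con, "fit", outcome = oc, qaic = qaic(fit),
                 converged = fit$converged)
        # serialized fit: coefficients, covariance, dispersion, qAIC
        fr <- list(coefficients = as.list(coef(fit)),
                   covariance = unname(fit$vcov),
                   loglik = fit$loglik, k = fit$k,
                   dispersion = dispersion(fit), qaic = qaic(fit),
                   n_strata = fit$n_strata, converged = fit$converged)
        jsonlite::write_json(fr, file.path(outdir, paste0("fit_", oc, ".json")),
                             digits = NA, auto_unbox = TRUE)
      }
    }
    if ("report" %in% stages) {
      rr_tab <- do.call(rbind, lapply(outcomes, function(oc) {
        main <- cbind(outcome = oc, variant = "main",
                      as.data.frame(results[[oc]]$lag_rr))
        var <- do.call(rbind, lapply(names(results[[oc]]$variants), function(v)
          cbind(outcome = oc, variant = v,
                as.data.frame(results[[oc]]$variants[[v]]))))
        rbind(main, var)
      }))
      utils::write.csv(rr_tab, file.path(outdir, "report_lag_rr.csv"),
                       row.names = FALSE)
      if (isTRUE(config$hours_model)) {
        qt <- do.call(rbind, lapply(outcomes, function(oc)
          cbind(outcome = oc, results[[oc]]$threshold_test$table)))
        utils::write.csv(qt, file.path(outdir, "report_qaic.csv"),
                         row.names = FALSE)
      }
      if (isTRUE(config$attributable)) {
        at <- do.call(rbind, lapply(outcomes, function(oc) {
          exposed <- et[et$exposed_8h_p1, c("county_id", "date")]
          a <- attributable(results[[oc]]$lag_rr, sim$counts, exposed,
                            outcome = oc)
          data.frame(outcome = oc, rr = a$rr, af = a$af,
                     exposed_hosp = a$exposed_hosp, excess = a$excess,
                     excess_lo = a$excess_lo, excess_hi = a$excess_hi)
        }))
        utils::write.csv(at, file.path(outdir, "report_attributable.csv"),
                         row.names = FALSE)
      }
      log_line(con, "report", tables = "written")
    }
  }
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
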