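# Stratum-conditioned Poisson likelihood: fitting, dispersion, qAIC and
# model selection.

#' Fit a conditional Poisson model by stratum absorption
#'
#' Maximizes the Poisson likelihood conditional on stratum outcome totals —
#' the within-stratum multinomial likelihood
#' `sum_s sum_i y_si log p_si(beta)` with
#' `p_si = exp(x_si' beta) / sum_j exp(x_sj' beta)` — by Newton-Raphson with
#' step halving. This is equivalent to Poisson regression with one dummy
#' intercept per stratum (profiled out), and coefficient estimates agree
#' with that fit to optimizer precision. Strata with zero outcome total or a
#' single row carry no information and are dropped before fitting.
#'
#' @param y non-negative outcome counts (non-integer values are accepted and
#'   treated in the quasi-likelihood sense).
#' @param X design matrix (no intercept; it is absorbed by the strata).
#' @param strata stratum identifiers, one per row.
#' @param tol convergence tolerance on the relative log-likelihood change.
#' @param maxit maximum Newton iterations.
#' @return object of class `cpfit`: coefficients, vcov, loglik (conditional
#'   multinomial scale, constants dropped), k (number of parameters),
#'   n_obs/n_strata (informative rows/strata), fitted (conditional means),
#'   y, strata (kept rows, fitting order), keep_idx (input row index of each
#'   kept row, so fitting-order vectors map back to the caller's rows),
#'   converged, iterations.
#' @export
fit_conditional_poisson <- function(y, X, strata, tol = 1e-8, maxit = 200L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  stopifnot(length(y) == nrow(X), length(strata) == nrow(X))
  if (any(y < 0)) stop("negative outcome counts")

  g0 <- factor(strata)
  tot <- tapply(y, g0, sum)
  sz <- tabulate(g0)
  informative <- levels(g0)[tot > 0 & sz >= 2L]
  keep <- g0 %in% informative
  if (!any(keep)) stop("no informative strata (positive total, >= 2 rows)")
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  g <- factor(as.character(g0[keep]))
  ord <- order(g)
  keep_idx <- which(keep)[ord]               # original row of each kept row
  y <- y[ord]; X <- X[ord, , drop = FALSE]; g <- g[ord]
  gi <- as.integer(g)
  n_g <- tabulate(gi)
  N <- as.vector(rowsum(y, gi))
  k <- ncol(X)

  loglik_parts <- function(beta) {
    eta <- as.vector(X %*% beta)
    etac <- eta - (as.vector(rowsum(eta, gi)) / n_g)[gi]
    E <- exp(etac)
    S <- as.vector(rowsum(E, gi))
    if (any(!is.finite(S)) || any(S <= 0)) return(NULL)
    p <- E / S[gi]
    list(ll = sum(y * etac) - sum(N * log(S)), p = p, m = N[gi] * p)
  }

  beta <- rep(0, k)
  parts <- loglik_parts(beta)
  ll <- parts$ll
  converged <- FALSE
  iter <- 0L
  H <- NULL
  repeat {
    iter <- iter + 1L
    m <- parts$m
    U <- crossprod(X, y - m)
    A <- crossprod(X, X * m)
    Ssum <- rowsum(X * m, gi)
    H <- A - crossprod(Ssum / sqrt(N))
    delta <- tryCatch(solve(H, U), error = function(e) NULL)
    if (is.null(delta)) break                  # singular information
    step <- 1
    repeat {
      cand <- beta + step * as.vector(delta)
      p2 <- loglik_parts(cand)
      if (!is.null(p2) && is.finite(p2$ll) && p2$ll >= ll - 1e-12) break
      step <- step / 2
      if (step < 1e-10) { p2 <- NULL; break }
    }
    if (is.null(p2)) break                     # no uphill step found
    improved <- p2$ll - ll
    beta <- beta + step * as.vector(delta)
    parts <- p2
    ll <- p2$ll
    if (abs(improved) <= tol * (abs(ll) + tol)) { converged <- TRUE; break }
    if (iter >= maxit) break
  }
  vcov <- tryCatch(solve(H), error = function(e) matrix(NA_real_, k, k))
  dimnames(vcov) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)
  out <- list(coefficients = beta, vcov = vcov, loglik = ll, k = k,
              n_obs = length(y), n_strata = nlevels(g),
              fitted = parts$m, y = y, strata = g, keep_idx = keep_idx,
              converged = converged, iterations = iter)
  class(out) <- "cpfit"
  out
}

#' @export
coef.cpfit <- function(object, ...) object$coefficients

#' @export
vcov.cpfit <- function(object, ...) object$vcov

#' @export
logLik.cpfit <- function(object, ...) {
  structure(object$loglik, df = object$k, class = "logLik")
}

#' @export
fitted.cpfit <- function(object, ...) object$fitted

#' @export
residuals.cpfit <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  r <- object$y - object$fitted
  if (type == "pearson") r <- r / sqrt(pmax(object$fitted, .Machine$double.eps))
  r
}

#' Simulate outcome counts from a conditional fit
#'
#' Draws new counts from the model the likelihood conditions on: within each
#' stratum the observed total is redistributed over its rows by a
#' multinomial draw with the fitted conditional probabilities. Useful for
#' parametric-bootstrap checks.
#'
#' @param object a `cpfit` (or [cco_fit()]) object.
#' @param nsim number of replicate count vectors.
#' @param seed optional RNG seed.
#' @param ... ignored.
#' @return data.frame with `nsim` columns (`sim_1`, ...), rows aligned with
#'   `object$y` / `object$strata` (fitting order; `object$keep_idx` maps
#'   them back to the rows passed to the fitter).
#' @export
simulate.cpfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) return(with_seed(seed, simulate(object, nsim = nsim)))
  gi <- as.integer(object$strata)
  N <- as.vector(rowsum(object$y, gi))
  p <- object$fitted / N[gi]
  idx <- split(seq_along(gi), gi)
  out <- matrix(0L, length(gi), nsim)
  for (ix in idx) {
    draws <- stats::rmultinom(nsim, size = round(sum(object$y[ix])), prob = p[ix])
    out[ix, ] <- draws
  }
  stats::setNames(as.data.frame(out), paste0("sim_", seq_len(nsim)))
}

#' @export
print.cpfit <- function(x, ...) {
  cat("Conditional Poisson fit:", x$k, "parameters,",
      x$n_obs, "rows in", x$n_strata, "strata\n")
  cat("log-likelihood (conditional):", format(x$loglik), "  converged:",
      x$converged, "\n")
  print(round(x$coefficients, 5))
  invisible(x)
}

#' Quasi-Poisson dispersion of a conditional fit
#'
#' Pearson statistic divided by the residual degrees of freedom, where the
#' absorbed stratum intercepts count as estimated parameters:
#' `df = n_obs - n_strata - k`.
#'
#' @param fit a `cpfit` (or [cco_fit()]) object.
#' @return the dispersion estimate (scalar).
#' @export
dispersion <- function(fit) {
  df <- fit$n_obs - fit$n_strata - fit$k
  if (df <= 0) stop("non-positive residual degrees of freedom")
  sum((fit$y - fit$fitted)^2 / fit$fitted) / df
}

#' Quasi-Akaike information criterion
#'
#' `qAIC = -2 loglik / c_hat + 2 k`, with `k` counting the free (non-
#' absorbed) parameters.
#'
#' @param fit a `cpfit` object.
#' @param c_hat dispersion estimate (default 1, i.e. ordinary AIC on the
#'   conditional likelihood).
#' @return scalar qAIC.
#' @export
qaic <- function(fit, c_hat = 1) {
  stopifnot(c_hat > 0)
  -2 * fit$loglik / c_hat + 2 * fit$k
}

#' Select among candidate fits by qAIC
#'
#' All candidates are scored with a common dispersion, estimated from the
#' richest candidate (most parameters), the standard quasi-likelihood
#' selection convention. Failed candidates (errors, non-convergence) are
#' excluded with a warning; ties are broken toward fewer parameters.
#'
#' @param fits named list of `cpfit`/`cco_fit` objects (entries may be NULL
#'   for candidates that failed to fit).
#' @return list with `table` (one row per candidate: k, loglik, qaic,
#'   converged), `best` (name of the winner), `c_hat`.
#' @export
select_model <- function(fits) {
  if (length(fits) < 2L) stop("need at least two candidate models")
  if (is.null(names(fits))) names(fits) <- paste0("model", seq_along(fits))
  ok <- vapply(fits, function(f) !is.null(f) && isTRUE(f$converged), logical(1))
  if (any(!ok))
    warning("candidate(s) excluded: ", paste(names(fits)[!ok], collapse = ", "))
  if (!any(ok)) stop("all candidate models failed")
  ks <- vapply(fits, function(f) if (is.null(f)) NA_integer_ else f$k, integer(1))
  rich <- names(fits)[ok][which.max(ks[ok])]
  c_hat <- dispersion(fits[[rich]])
  qa <- rep(NA_real_, length(fits))
  qa[ok] <- vapply(fits[ok], qaic, numeric(1), c_hat = c_hat)
  tab <- data.frame(model = names(fits), k = ks,
                    loglik = vapply(fits, function(f)
                      if (is.null(f)) NA_real_ else f$loglik, numeric(1)),
                    qaic = qa, converged = ok,
                    stringsAsFactors = FALSE, row.names = NULL)
  cand <- which(ok)
  best <- cand[order(qa[cand], ks[cand])][1]
  list(table = tab, best = names(fits)[best], c_hat = c_hat)
}
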