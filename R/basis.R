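# Natural-spline bases and the exposure-history x lag cross-basis.

#' Natural cubic spline basis
#'
#' Thin wrapper around `splines::ns` that fixes the knot convention used
#' throughout the package: `df` columns, no intercept, `df - 1` interior
#' knots at equally spaced quantiles of the data, boundary knots at the data
#' range (the basis is linear beyond them). `kind = "linear"` returns the
#' single centered column `x - mean(x)`.
#'
#' @param x numeric values.
#' @param df degrees of freedom (columns).
#' @param kind `"natural_cubic"` or `"linear"` (df is forced to 1).
#' @param knots,boundary optional explicit interior/boundary knots.
#' @return basis matrix with an `"ns_meta"` attribute allowing evaluation at
#'   new values via [eval_basis()].
#' @export
natural_spline_basis <- function(x, df, kind = c("natural_cubic", "linear"),
                                 knots = NULL, boundary = NULL) {
  kind <- match.arg(kind)
  if (kind == "linear") {
    ctr <- mean(x)
    B <- matrix(x - ctr, ncol = 1, dimnames = list(NULL, "x"))
    attr(B, "ns_meta") <- list(kind = "linear", center = ctr)
    return(B)
  }
  if (df > length(unique(x)))
    stop("df (", df, ") exceeds the number of distinct x values")
  if (is.null(boundary)) boundary <- range(x)
  if (is.null(knots) && df >= 2L) {
    probs <- seq_len(df - 1L) / df
    knots <- stats::quantile(x, probs = probs, names = FALSE, type = 7)
    # zero-inflated covariates (precipitation) can drive quantile knots onto
    # the boundary; fall back to quantiles of the interior values
    if (any(knots <= boundary[1] | knots >= boundary[2])) {
      inner <- x[x > boundary[1] & x < boundary[2]]
      if (length(inner) >= df)
        knots <- stats::quantile(inner, probs = probs, names = FALSE, type = 7)
    }
  }
  B <- splines::ns(x, knots = knots, Boundary.knots = boundary)
  meta <- list(kind = "natural_cubic", knots = knots, boundary = boundary)
  B <- unclass(B)[, , drop = FALSE]
  attr(B, "ns_meta") <- meta
  B
}

#' Evaluate a stored spline basis at new values
#'
#' @param meta the `"ns_meta"` attribute of a [natural_spline_basis()] (or a
#'   cross-basis var component).
#' @param x new values.
#' @return basis matrix at `x`.
#' @export
eval_basis <- function(meta, x) {
  if (meta$kind == "linear")
    return(matrix(x - meta$center, ncol = 1))
  if (meta$kind %in% c("identity", "binary"))
    return(matrix(x, ncol = 1))
  unclass(splines::ns(x, knots = meta$knots, Boundary.knots = meta$boundary))
}

#' Constrained lag basis over lags 0-6
#'
#' With `df = 7` the basis is the identity (seven per-lag indicators,
#' unconstrained). Otherwise it is an intercept column plus a natural cubic
#' spline with `df - 1` columns over the lag values, interior knots at
#' equally spaced quantiles of 0..6 and boundary knots at 0 and 6 — so a
#' `df`-dimensional basis has `df - 2` interior knots (3, 4 and 5 df
#' correspond to 1, 2 and 3 knots).
#'
#' @param df degrees of freedom, 2-7.
#' @param lags lag values (fixed design: 0:6).
#' @return length(lags) x df matrix.
#' @export
lag_basis <- function(df, lags = 0:6) {
  df <- as.integer(df)
  if (df > length(lags))
    stop("lag basis df (", df, ") cannot exceed the number of lags (",
         length(lags), ")")
  if (df < 2L) stop("lag basis needs df >= 2")
  if (df == length(lags)) {
    L <- diag(length(lags))
    dimnames(L) <- list(NULL, paste0("lag", lags))
    return(L)
  }
  kn <- if (df >= 3L)
    stats::quantile(lags, probs = seq_len(df - 2L) / (df - 1L), names = FALSE,
                    type = 7) else NULL
  S <- unclass(splines::ns(lags, knots = kn, Boundary.knots = range(lags)))
  L <- cbind(1, S)
  dimnames(L) <- list(NULL, c("l_const", paste0("l_s", seq_len(ncol(S)))))
  L
}

#' Exposure-history x lag cross-basis
#'
#' Tensor-product design for a distributed lag (non-linear) model: with
#' exposure histories `x[t - l]`, `l = 0..6`, var-dimension basis functions
#' `v_j` and lag basis `L`, the design columns are
#' `sum_l v_j(x[t-l]) * L[l, k]`. With the identity var basis (binary or
#' linear exposure) and `lag_df = 7` this reduces to the matrix of seven
#' lagged exposure copies.
#'
#' @param hist n x 7 matrix of exposure histories, columns lag 0..6.
#' @param var_kind `"linear"` (identity transform; also used for binary
#'   exposure) or `"ns"` (natural cubic spline with `var_df` columns).
#' @param var_df degrees of freedom of the var dimension when `var_kind`
#'   is `"ns"`.
#' @param lag_df lag-basis degrees of freedom (2-7).
#' @param var_knots,var_boundary optional explicit knots for the var spline.
#' @return list with `X` (n x var_df*lag_df design block) and `meta`
#'   (var/lag basis metadata for back-transformation, see [cb_contrast()]).
#' @export
cross_basis <- function(hist, var_kind = c("linear", "ns"), var_df = 1L,
                        lag_df = 5L, var_knots = NULL, var_boundary = NULL) {
  var_kind <- match.arg(var_kind)
  hist <- as.matrix(hist)
  if (ncol(hist) != 7L) stop("hist must have 7 columns (lags 0-6)")
  L <- lag_basis(lag_df)
  if (var_kind == "linear") {
    var_meta <- list(kind = "identity")
    V <- list(hist)
  } else {
    xall <- as.vector(hist)
    if (is.null(var_boundary)) var_boundary <- range(xall)
    if (is.null(var_knots) && var_df >= 2L)
      var_knots <- stats::quantile(xall[xall > min(xall)],
                                   probs = seq_len(var_df - 1L) / var_df,
                                   names = FALSE, type = 7)
    var_meta <- list(kind = "natural_cubic", knots = var_knots,
                     boundary = var_boundary)
    VB <- eval_basis(var_meta, xall)
    V <- lapply(seq_len(ncol(VB)), function(j)
      matrix(VB[, j], nrow(hist), ncol(hist)))
  }
  blocks <- lapply(seq_along(V), function(j) {
    B <- V[[j]] %*% L
    colnames(B) <- paste0("v", j, "_", colnames(L))
    B
  })
  X <- do.call(cbind, blocks)
  meta <- list(var = var_meta, L = L, lag_df = as.integer(lag_df),
               var_dim = length(V), ncol = ncol(X))
  list(X = X, meta = meta)
}

# value of the var basis at a scalar exposure level
var_value <- function(var_meta, x) {
  if (var_meta$kind %in% c("identity", "binary", "linear")) return(x)
  as.vector(eval_basis(var_meta, x))
}

#' Per-lag contrast matrix for a cross-basis
#'
#' Linear map from the cross-basis coefficient block to the seven per-lag
#' log rate ratios for the exposure contrast `x1` versus `x0`: row `l` of the
#' returned matrix dotted with the coefficients gives the log-RR at lag `l`.
#'
#' @param meta cross-basis metadata from [cross_basis()].
#' @param x1,x0 exposure levels contrasted (default exposed 1 vs unexposed 0).
#' @return 7 x ncol matrix.
#' @export
cb_contrast <- function(meta, x1 = 1, x0 = 0) {
  dv <- var_value(meta$var, x1) - var_value(meta$var, x0)
  kronecker(matrix(dv, nrow = 1), meta$L)
}
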