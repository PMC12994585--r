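test_that("two-cell stratum has the closed-form conditional MLE", {
  # one stratum, two days, binary exposure: the conditional likelihood is
  # binomial and the MLE of the log rate ratio is log(y1/y0)
  y <- c(2, 1)
  X <- matrix(c(1, 0), ncol = 1)
  fit <- fit_conditional_poisson(y, X, c("s", "s"))
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)), log(2), tolerance = 1e-7)
  # the variance of log(y1/y0) is 1/y1 + 1/y0
  expect_equal(unname(diag(vcov(fit))), 1 / 2 + 1 / 1, tolerance = 1e-3)
  # fitted values split the stratum total by the conditional probabilities
  expect_equal(sum(fitted(fit)), 3)
})

test_that("conditional fit agrees with the stratum-dummy GLM oracle", {
  set.seed(101)
  for (i in 1:5) {
    d <- random_small_dataset(n_strata = 30L, k = 4L)
    fit <- fit_conditional_poisson(d$y, d$X, d$strata)
    orc <- oracle_glm_fit(d$y, d$X, d$strata)
    expect_true(fit$converged)
    expect_equal(unname(coef(fit)), orc$coef, tolerance = 1e-6)
    expect_lt(max(abs(vcov(fit) - orc$vcov)), 1e-6)
  }
})

test_that("uninformative strata are dropped and bad inputs rejected", {
  y <- c(1, 2, 0, 0, 5)
  X <- matrix(stats::rnorm(5), ncol = 1)
  strata <- c("a", "a", "b", "b", "c")
  fit <- fit_conditional_poisson(y, X, strata)
  expect_equal(fit$n_strata, 1L)       # b has total 0, c is a singleton
  expect_equal(fit$n_obs, 2L)
  expect_error(fit_conditional_poisson(c(-1, 1), X[1:2, , drop = FALSE],
                                       c("a", "a")), "negative")
  expect_error(fit_conditional_poisson(c(0, 0), X[1:2, , drop = FALSE],
                                       c("a", "a")), "no informative strata")
})

test_that("the likelihood is invariant to large stratum offsets", {
  # per-stratum centering must protect against overflow from extreme
  # baseline differences
  set.seed(102)
  d <- random_small_dataset(n_strata = 20L, k = 2L)
  X2 <- d$X
  X2[, 1] <- X2[, 1] + 300 * (d$strata %% 2)  # huge between-stratum shift
  f1 <- fit_conditional_poisson(d$y, d$X, d$strata)
  # shifting a column by a stratum-constant leaves the conditional
  # likelihood unchanged at the optimum
  shift <- 300 * (d$strata %% 2)
  X3 <- cbind(d$X[, 1] + shift, d$X[, 2])
  f3 <- fit_conditional_poisson(d$y, X3, d$strata)
  expect_equal(unname(coef(f3)), unname(coef(f1)), tolerance = 1e-6)
  expect_equal(f3$loglik, f1$loglik, tolerance = 1e-8)
})

test_that("dispersion and qAIC follow their definitions", {
  set.seed(103)
  d <- random_small_dataset(n_strata = 40L, k = 2L)
  fit <- fit_conditional_poisson(d$y, d$X, d$strata)
  pearson <- sum((fit$y - fit$fitted)^2 / fit$fitted)
  expect_equal(dispersion(fit),
               pearson / (fit$n_obs - fit$n_strata - fit$k))
  expect_equal(qaic(fit), -2 * fit$loglik + 2 * fit$k)
  expect_equal(qaic(fit, c_hat = 2), -fit$loglik + 2 * fit$k)
  expect_error(qaic(fit, c_hat = 0))
  # Poisson data should give dispersion near 1
  expect_equal(dispersion(fit), 1, tolerance = 0.35)
})

test_that("model selection uses a common dispersion and parsimony ties", {
  set.seed(104)
  d <- random_small_dataset(n_strata = 60L, k = 3L)
  f_small <- fit_conditional_poisson(d$y, d$X[, 1, drop = FALSE], d$strata)
  f_big <- fit_conditional_poisson(d$y, d$X, d$strata)
  sel <- select_model(list(small = f_small, big = f_big))
  expect_equal(sel$c_hat, dispersion(f_big))     # richest candidate
  expect_equal(sel$table$qaic,
               c(qaic(f_small, sel$c_hat), qaic(f_big, sel$c_hat)))
  # an exact tie goes to the fewer-parameter model
  sel2 <- select_model(list(a = f_big, b = f_big, c = f_small))
  expect_true(sel2$best %in% c("a", "b", "c"))
  expect_warning(sel3 <- select_model(list(a = f_big, b = NULL)), "excluded")
  expect_equal(sel3$best, "a")
})

test_that("simulate redistributes stratum totals with the fitted probabilities", {
  set.seed(105)
  d <- random_small_dataset(n_strata = 50L, k = 2L)
  fit <- fit_conditional_poisson(d$y, d$X, d$strata)
  s <- simulate(fit, nsim = 3, seed = 77)
  expect_equal(dim(s), c(fit$n_obs, 3L))
  gi <- as.integer(fit$strata)
  for (j in 1:3)
    expect_equal(as.vector(rowsum(s[[j]], gi)),
                 as.vector(rowsum(fit$y, gi)))
  # seeded draws reproduce
  expect_identical(s, simulate(fit, nsim = 3, seed = 77))
  # keep_idx maps simulated rows back to the input rows; refitting the
  # simulated data recovers coefficients within sampling noise
  Xo <- d$X[fit$keep_idx, , drop = FALSE]
  go <- d$strata[fit$keep_idx]
  expect_equal(fit$y, d$y[fit$keep_idx])
  ests <- vapply(1:3, function(j)
    coef(fit_conditional_poisson(s[[j]], Xo, go))[1], numeric(1))
  expect_equal(mean(ests), unname(coef(fit)[1]), tolerance = 0.2)
})
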