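test_that("two-cell stratum has the closed-form conditional MLE", {
  d <- data.frame(y = c(1, 2), x = c(0, 1), s = "a")
  fit <- ccpois(y ~ x, d, strata = s)
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)), log(2), tolerance = 1e-9)
  # mirrored strata force the score to vanish at zero
  d2 <- data.frame(y = c(1, 2, 1, 2), x = c(0, 1, 1, 0), s = rep(c("a", "b"), each = 2))
  expect_equal(unname(coef(ccpois(y ~ x, d2, strata = s))), 0, tolerance = 1e-9)
})

test_that("conditional MLE matches grid search and conditional-logistic oracles", {
  set.seed(12)
  for (i in 1:10) {
    d <- random_small_instance()
    b_hat <- unname(coef(ccpois(y ~ x, d, strata = s)))
    expect_lt(abs(b_hat - grid_search_mle(d$y, d$x, d$s)), 1e-6)
    expect_lt(abs(b_hat - clogit_mle(d$y, d$x, d$s)), 1e-6)
  }
})

test_that("degenerate data are handled: inestimable slopes, dropped strata, missing rows", {
  d <- data.frame(y = c(1, 2, 3, 4), x = c(1, 1, 2, 2), s = c("a", "a", "b", "b"))
  expect_error(ccpois(y ~ x, d, strata = s), "inestimable")

  d2 <- data.frame(y = c(1, 2, 0, 0, 3, 1), x = c(0, 1, 0, 1, 0.5, 1.5),
                   s = rep(c("a", "zero", "c"), each = 2))
  fit <- ccpois(y ~ x, d2, strata = s)
  expect_identical(fit$n_strata_dropped, 1L)   # the zero-total stratum
  expect_identical(fit$n_strata, 2L)

  d3 <- data.frame(y = c(1, 2, NA, 2, 1, 4), x = c(0, 1, 2, 0, 1, NA),
                   s = rep(c("a", "b", "c"), each = 2))
  fit3 <- ccpois(y ~ x, d3, strata = s)
  expect_identical(fit3$n_days_dropped, 2L)
  expect_identical(fit3$n_strata_dropped, 2L)  # both reduced to singletons
  expect_error(ccpois(y ~ x, data.frame(y = 0, x = 1, s = "a"), strata = s),
               "no informative strata")
  expect_error(ccpois(y ~ x, data.frame(y = c(1.5, 2), x = c(0, 1), s = "a"),
                      strata = s), "integer counts")
})

test_that("estimates are invariant to stratum-constant exposure shifts", {
  set.seed(13)
  for (i in 1:5) {
    d <- random_small_instance()
    b0 <- coef(ccpois(y ~ x, d, strata = s))
    shift <- rnorm(length(unique(d$s)), 0, 10)
    d$x2 <- d$x + shift[match(d$s, unique(d$s))]
    expect_equal(unname(coef(ccpois(y ~ x2, d, strata = s))), unname(b0),
                 tolerance = 1e-7)
  }
})

test_that("fitted means conserve the stratum totals and probabilities sum to 1", {
  set.seed(14)
  d <- random_small_instance(n_strata = 5)
  fit <- ccpois(y ~ x, d, strata = s)
  mu <- fitted(fit)
  expect_equal(as.numeric(rowsum(mu, fit$strata)),
               as.numeric(rowsum(fit$y, fit$strata)), tolerance = 1e-8)
  # conditional simulation preserves the totals exactly
  sims <- simulate(fit, nsim = 3, seed = 99)
  for (j in 1:3)
    expect_identical(as.numeric(rowsum(sims[[j]], fit$strata)),
                     as.numeric(rowsum(fit$y, fit$strata)))
})

test_that("dispersion is the Pearson statistic over residual degrees of freedom", {
  set.seed(15)
  n <- 60
  d <- data.frame(s = rep(1:15, each = 4), x = rnorm(n))
  d$y <- rpois(n, 5)
  d <- d[tapply(d$y, d$s, sum)[d$s] > 0, ]
  fit <- ccpois(y ~ x, d, strata = s)
  phi_manual <- sum((fit$y - fitted(fit))^2 / fitted(fit)) /
    (fit$n - fit$n_strata - 1L)
  expect_equal(fit$dispersion, phi_manual)
  expect_equal(pearson_dispersion(fit), phi_manual)
  expect_equal(vcov(fit), vcov(fit, scaled = FALSE) * fit$dispersion)
  # saturated fit: no residual df, dispersion falls back to 1 in the fit
  sat <- ccpois(y ~ x, data.frame(y = c(1, 2), x = c(0, 1), s = "a"), strata = s)
  expect_identical(sat$dispersion, 1)
  expect_error(pearson_dispersion(sat), "degrees of freedom")
})

test_that("quasi-Poisson scaling widens standard errors by sqrt(phi)", {
  set.seed(16)
  n <- 400
  d <- data.frame(s = rep(1:100, each = 4), x = rnorm(n))
  d$y <- rnbinom(n, size = 2, mu = 8)  # overdispersed
  fit <- ccpois(y ~ x, d, strata = s)
  expect_gt(fit$dispersion, 1.5)
  expect_equal(unname(fit$se), sqrt(diag(fit$vcov) * fit$dispersion),
               ignore_attr = TRUE)
})

test_that("predict returns relative rates and summary prints a coefficient table", {
  set.seed(17)
  d <- random_small_instance(n_strata = 4)
  fit <- ccpois(y ~ x, d, strata = s)
  nd <- data.frame(x = c(0, 1, 2))
  expect_equal(predict(fit, nd, type = "risk"), exp(predict(fit, nd)))
  expect_equal(unname(predict(fit, nd)[1]), 0)
  expect_output(print(fit), "Conditional quasi-Poisson")
  expect_output(print(summary(fit)), "dispersion")
  ci <- confint(fit)
  expect_lt(ci[1, 1], coef(fit)[1])
  expect_gt(ci[1, 2], coef(fit)[1])
})

test_that("RR per IQR transforms the slope and interval to the reporting scale", {
  fake <- structure(list(coefficients = c(x = 0.01), se = c(x = 0.005),
                         p.value = c(x = 0.045), converged = TRUE),
                    class = "ccpois")
  est <- rr_per_iqr(fake, 10)
  expect_equal(est$rr, 1.105171, tolerance = 1e-6)
  expect_equal(est$rr_low, 1.002002, tolerance = 1e-6)
  expect_equal(est$rr_high, 1.218962, tolerance = 1e-6)

  null <- structure(list(coefficients = c(x = 0), se = c(x = 0.01),
                         p.value = c(x = 1), converged = TRUE), class = "ccpois")
  e0 <- rr_per_iqr(null, 7)
  expect_equal(e0$rr, 1)
  expect_equal(log(e0$rr_high), -log(e0$rr_low))  # symmetric on the log scale

  exact <- structure(list(coefficients = c(x = log(1.06) / 16), se = c(x = 0),
                          p.value = c(x = 0), converged = TRUE), class = "ccpois")
  expect_equal(rr_per_iqr(exact, 16)$rr, 1.06)

  # monotone in beta for fixed IQR
  rrs <- vapply(seq(-0.02, 0.02, by = 0.005), function(b) {
    f <- structure(list(coefficients = c(x = b), se = c(x = 0.01),
                        p.value = c(x = 1), converged = TRUE), class = "ccpois")
    rr_per_iqr(f, 10)$rr
  }, numeric(1))
  expect_true(all(diff(rrs) > 0))
  expect_error(rr_per_iqr(fake, 0), "positive")
})
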