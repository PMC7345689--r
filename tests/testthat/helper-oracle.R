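# Independent oracles for the conditional-Poisson fitter.  Both are written
# naively (double loops, no shared code with the package internals) so they
# stay independent of the path they check.

# Within-stratum multinomial log-likelihood, brute force.
naive_cond_loglik <- function(beta, y, x, s) {
  ll <- 0
  for (st in unique(s)) {
    i <- which(s == st)
    eta <- beta * x[i]
    ll <- ll + sum(y[i] * eta) - sum(y[i]) * log(sum(exp(eta)))
  }
  ll
}

# Maximiser of the conditional log-likelihood by 1-D optimisation.
grid_search_mle <- function(y, x, s, interval = c(-10, 10)) {
  optimize(function(b) naive_cond_loglik(b, y, x, s),
           interval = interval, maximum = TRUE, tol = 1e-12)$maximum
}

# Conditional-logistic estimate on the expanded event-level data: each of
# the sum(y) events becomes a case matched to the other days of its stratum.
clogit_mle <- function(y, x, s) {
  day <- rep(seq_along(y), y)
  ev <- do.call(rbind, lapply(seq_along(day), function(e) {
    i <- day[e]
    rows <- which(s == s[i])
    data.frame(event = e, case = as.integer(rows == i), x = x[rows])
  }))
  ev$one <- 1
  m <- survival::coxph(survival::Surv(one, case) ~ x + survival::strata(event),
                       data = ev, method = "exact")
  unname(coef(m))
}

# Random small instance with within-stratum exposure variation and
# positive totals everywhere.
random_small_instance <- function(n_strata = sample(2:5, 1),
                                  max_days = 6L) {
  repeat {
    sizes <- sample(2:max_days, n_strata, replace = TRUE)
    s <- rep(seq_len(n_strata), sizes)
    x <- round(rnorm(length(s)), 2)
    y <- rpois(length(s), 2)
    ok <- all(tapply(y, s, sum) > 0) &&
      all(tapply(x, s, function(v) length(unique(v)) > 1))
    if (ok) return(data.frame(y = y, x = x, s = s))
  }
}
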