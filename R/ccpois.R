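#' Conditional quasi-Poisson regression with stratum elimination
#'
#' Fits the statistical core of the time-stratified case-crossover
#' analysis: a Poisson log-linear model for daily counts whose
#' stratum-specific intercepts are eliminated by conditioning on the
#' stratum totals.  Within a stratum `s` with days `i`, counts `y_si`
#' and linear predictor `eta_si = x_si' beta`, the conditional likelihood
#' is multinomial with cell probabilities
#' `p_si = exp(eta_si) / sum_j exp(eta_sj)`; the stratum intercepts are
#' never estimated.  This is algebraically identical to the
#' `eliminate = factor(stratum)` formulation of generalized nonlinear
#' model software, and — for event-level data — to conditional logistic
#' regression on the case-crossover referent sets.
#'
#' Estimation is by direct Newton maximisation of the conditional
#' log-likelihood with analytic gradient and Hessian (with step-halving),
#' declared converged when the relative log-likelihood change is below
#' `1e-10` and every score component is below `1e-8` relative to its
#' natural magnitude (the floating-point floor of the score grows with
#' the total count, so a fixed absolute threshold is unattainable for
#' very large datasets).
#' Overdispersion is handled in the quasi-Poisson way: the Pearson
#' dispersion (see [pearson_dispersion()]) scales the model-based
#' variance, and all reported standard errors, confidence intervals and
#' p-values use the scaled variance.
#'
#' Rows with missing response, covariates or stratum are excluded before
#' fitting; strata that are left with fewer than 2 rows or a zero total
#' count carry no conditional information and are dropped (both
#' exclusions are counted in the returned object).  A covariate with no
#' variation within any stratum makes its coefficient inestimable and is
#' an error.
#'
#' @param formula model formula, e.g.
#'   `count ~ no2_lag1 + nsb(temp_lag1, 3)`.  Any intercept is ignored
#'   (it is absorbed by the strata).
#' @param data data frame containing the model variables.
#' @param strata stratum labels, evaluated in `data` (e.g. a column name);
#'   typically produced by [stratum_labels()].
#' @return An object of class `"ccpois"` with components `coefficients`,
#'   `vcov` (unscaled), `dispersion`, `se` (dispersion-scaled),
#'   `loglik`, `fitted.values` (within-stratum conditional means), `y`,
#'   `strata`, `n`, `n_strata`, `n_days_dropped`, `n_strata_dropped`,
#'   `converged`, `iter`, `max_score`, `df.residual`.
#' @examples
#' d <- data.frame(y = c(1, 2), x = c(0, 1), s = c("a", "a"))
#' coef(ccpois(y ~ x, d, strata = s))  # log(2)
#' @seealso [rr_per_iqr()] to scale a coefficient to an RR per IQR,
#'   [run_grid()] for the full analysis grid.
#' @export
ccpois <- function(formula, data, strata) {
  cl <- match.call()
  mf <- model.frame(formula, data = data, na.action = na.pass)
  mt <- attr(mf, "terms")
  y <- model.response(mf)
  X <- model.matrix(mt, mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  if (ncol(X) == 0L) stop("model has no covariates")
  s <- eval(substitute(strata), data, parent.frame())
  if (length(s) != length(y))
    stop("'strata' must have one label per row of 'data'")

  keep <- !is.na(y) & complete.cases(X) & !is.na(s)
  n_days_dropped <- sum(!keep)
  y <- y[keep]; X <- X[keep, , drop = FALSE]; s <- factor(s[keep])
  if (any(y < 0) || any(y != round(y)))
    stop("response must be non-negative integer counts")

  # drop non-informative strata: < 2 days or zero total count
  size <- tabulate(s, nbins = nlevels(s))
  tot <- as.numeric(rowsum(y, s))
  bad_strata <- size < 2L | tot == 0
  n_strata_dropped <- sum(bad_strata)
  keep2 <- !bad_strata[as.integer(s)]
  y <- y[keep2]; X <- X[keep2, , drop = FALSE]; s <- droplevels(s[keep2])
  if (nlevels(s) == 0L)
    stop("no informative strata (need >= 2 days and a non-zero total)")

  si <- as.integer(s)
  Ytot <- as.numeric(rowsum(y, s))

  # estimability: every covariate must vary within at least one stratum
  sm <- rowsum(X, s) / tabulate(si)
  Xc <- X - sm[si, , drop = FALSE]
  scale_x <- pmax(apply(abs(X), 2, max), 1)
  degenerate <- sqrt(colSums(Xc^2)) < 1e-10 * scale_x
  if (any(degenerate))
    stop("coefficient inestimable: no within-stratum variation in ",
         paste(colnames(X)[degenerate], collapse = ", "))

  fit <- .ccpois_newton(y, X, si, Ytot)

  phi_info <- .pearson_phi(y, fit$mu, n_strata = nlevels(s), p = ncol(X),
                           strict = FALSE)
  se <- sqrt(diag(fit$vcov) * phi_info$phi)
  z <- fit$beta / se
  structure(list(
    coefficients = setNames(fit$beta, colnames(X)),
    vcov = structure(fit$vcov, dimnames = list(colnames(X), colnames(X))),
    se = setNames(se, colnames(X)),
    p.value = setNames(2 * pnorm(-abs(z)), colnames(X)),
    dispersion = phi_info$phi,
    pearson = phi_info$pearson,
    df.residual = phi_info$df,
    loglik = fit$loglik,
    fitted.values = fit$mu,
    y = y, strata = s,
    n = length(y), n_strata = nlevels(s),
    n_days_dropped = n_days_dropped, n_strata_dropped = n_strata_dropped,
    converged = fit$converged, iter = fit$iter, max_score = fit$max_score,
    terms = mt, call = cl
  ), class = "ccpois")
}

## Newton-Raphson on the within-stratum multinomial log-likelihood.
## si: integer stratum id per row, Ytot: stratum totals (by id order).
.ccpois_newton <- function(y, X, si, Ytot, maxit = 100L,
                           tol_ll = 1e-10, tol_score = 1e-8) {
  p <- ncol(X)
  beta <- rep(0, p)
  idx <- split(seq_along(y), si)
  ll_at <- function(eta) {
    amax <- vapply(idx, function(i) max(eta[i]), numeric(1))
    w <- exp(eta - amax[si])
    denom <- as.numeric(rowsum(w, si))
    list(ll = sum(y * eta) - sum(Ytot * (log(denom) + amax)),
         w = w, denom = denom)
  }
  eta <- drop(X %*% beta)
  st <- ll_at(eta)
  ll <- st$ll
  converged <- FALSE
  max_score <- Inf
  H <- NULL
  for (iter in seq_len(maxit)) {
    prob <- st$w / st$denom[si]
    mu <- Ytot[si] * prob
    g <- drop(crossprod(X, y - mu))
    S <- rowsum(X * mu, si)
    H <- crossprod(X, X * mu) - crossprod(S / sqrt(Ytot))
    max_score <- max(abs(g))
    step <- tryCatch(solve(H, g), error = function(e)
      stop("singular Hessian: collinear covariates or no usable within-stratum variation"))
    # step-halving if the likelihood does not improve
    lambda <- 1
    repeat {
      beta_new <- beta + lambda * step
      st_new <- ll_at(drop(X %*% beta_new))
      if (is.finite(st_new$ll) && st_new$ll >= ll - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-10) break
    }
    rel <- abs(st_new$ll - ll) / (abs(ll) + 1e-10)
    beta <- beta_new
    st <- st_new
    ll_old <- ll
    ll <- st$ll
    # recompute score at the new beta for the convergence check; the score
    # tolerance is scaled per column by the magnitude of the summed terms,
    # since the achievable floor grows with the total count
    prob <- st$w / st$denom[si]
    mu <- Ytot[si] * prob
    g <- drop(crossprod(X, y - mu))
    gscale <- pmax(1, colSums(abs(X) * mu))
    max_score <- max(abs(g) / gscale)
    if (rel < tol_ll && max_score < tol_score) {
      converged <- TRUE
      break
    }
  }
  prob <- st$w / st$denom[si]
  mu <- Ytot[si] * prob
  S <- rowsum(X * mu, si)
  H <- crossprod(X, X * mu) - crossprod(S / sqrt(Ytot))
  vcov <- tryCatch(solve(H), error = function(e)
    stop("singular Hessian at the optimum"))
  list(beta = beta, vcov = vcov, mu = mu, loglik = ll,
       converged = converged, iter = iter, max_score = max_score)
}

## Pearson dispersion and residual degrees of freedom.  With strict = FALSE
## a non-positive df falls back to phi = 1 (model-based Poisson variance),
## so that tiny saturated datasets remain fittable.
.pearson_phi <- function(y, mu, n_strata, p, strict = TRUE) {
  pearson <- sum((y - mu)^2 / mu)
  df <- length(y) - n_strata - p
  if (df <= 0) {
    if (strict) stop("non-positive residual degrees of freedom")
    return(list(phi = 1, pearson = pearson, df = df))
  }
  list(phi = pearson / df, pearson = pearson, df = df)
}

#' Pearson dispersion of a fitted conditional Poisson model
#'
#' The quasi-Poisson dispersion: the Pearson statistic
#' `sum((y - mu)^2 / mu)` over the retained days, divided by the
#' residual degrees of freedom `n_days - n_strata - p` (the eliminated
#' stratum intercepts count as estimated parameters).  Fitted means
#' `mu` distribute each stratum's observed total over its days by the
#' fitted multinomial probabilities, so they sum to the observed total
#' within every stratum.
#'
#' @param fit a `"ccpois"` fit.
#' @return The dispersion estimate, a single number.
#' @export
pearson_dispersion <- function(fit) {
  stopifnot(inherits(fit, "ccpois"))
  .pearson_phi(fit$y, fit$fitted.values, fit$n_strata,
               length(fit$coefficients))$phi
}

#' @export
print.ccpois <- function(x, digits = 4, ...) {
  cat("Conditional quasi-Poisson fit (time-stratified case-crossover)\n")
  cat(sprintf("  %d days in %d strata (%d days, %d strata dropped)\n",
              x$n, x$n_strata, x$n_days_dropped, x$n_strata_dropped))
  cat(sprintf("  dispersion phi = %.*g; %sconverged in %d iterations\n",
              digits, x$dispersion, if (x$converged) "" else "NOT ", x$iter))
  cat("Coefficients:\n")
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
summary.ccpois <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients,
               `Std. Error` = object$se,
               `z value` = object$coefficients / object$se,
               `Pr(>|z|)` = object$p.value)
  structure(list(coefficients = tab, dispersion = object$dispersion,
                 n = object$n, n_strata = object$n_strata,
                 converged = object$converged, call = object$call),
            class = "summary.ccpois")
}

#' @export
print.summary.ccpois <- function(x, ...) {
  cat("Call: "); print(x$call)
  cat(sprintf("%d days, %d strata; quasi-Poisson dispersion %.4g\n",
              x$n, x$n_strata, x$dispersion))
  printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' @export
coef.ccpois <- function(object, ...) object$coefficients

#' Variance-covariance of a conditional Poisson fit
#'
#' @param object a `"ccpois"` fit.
#' @param scaled if `TRUE` (default) the matrix is multiplied by the
#'   Pearson dispersion (quasi-Poisson variance); if `FALSE` the
#'   model-based Poisson variance is returned.
#' @param ... unused.
#' @export
vcov.ccpois <- function(object, scaled = TRUE, ...) {
  if (scaled) object$vcov * object$dispersion else object$vcov
}

#' @export
fitted.ccpois <- function(object, ...) object$fitted.values

#' @export
residuals.ccpois <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  r <- object$y - object$fitted.values
  if (type == "pearson") r <- r / sqrt(object$fitted.values)
  r
}

#' @export
confint.ccpois <- function(object, parm, level = 0.95, ...) {
  cf <- object$coefficients
  if (missing(parm)) parm <- names(cf)
  z <- qnorm(1 - (1 - level) / 2)
  out <- cbind(cf[parm] - z * object$se[parm], cf[parm] + z * object$se[parm])
  colnames(out) <- sprintf("%.1f %%", 100 * c((1 - level) / 2, 1 - (1 - level) / 2))
  out
}

#' Predict from a conditional Poisson fit
#'
#' Because stratum intercepts are eliminated, absolute rates are not
#' identified; predictions are relative: the linear predictor
#' `x' beta` (type `"link"`) or the relative rate `exp(x' beta)`
#' (type `"risk"`), interpretable within a stratum.
#'
#' @param object a `"ccpois"` fit.
#' @param newdata data frame of covariate values; defaults to the data
#'   the model was fitted to.
#' @param type `"link"` or `"risk"`.
#' @param ... unused.
#' @export
predict.ccpois <- function(object, newdata = NULL, type = c("link", "risk"), ...) {
  type <- match.arg(type)
  if (is.null(newdata))
    stop("predict.ccpois requires 'newdata'; within-sample conditional means are in fitted()")
  tt <- delete.response(terms(object))
  mf <- model.frame(tt, newdata, na.action = na.pass)
  X <- model.matrix(tt, mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  eta <- drop(X %*% object$coefficients)
  if (type == "risk") exp(eta) else eta
}

#' Simulate counts from a fitted conditional model
#'
#' Draws new within-stratum count vectors conditional on the observed
#' stratum totals, i.e. multinomial draws with the fitted cell
#' probabilities — the generative model the conditional likelihood
#' actually describes.
#'
#' @param object a `"ccpois"` fit.
#' @param nsim number of simulated response vectors.
#' @param seed optional seed passed to `set.seed()`.
#' @param ... unused.
#' @return A data frame with `nsim` columns, rows aligned to the rows
#'   used in the fit.
#' @export
simulate.ccpois <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  si <- as.integer(object$strata)
  prob <- object$fitted.values / as.numeric(rowsum(object$fitted.values,
                                                  object$strata))[si]
  idx <- split(seq_along(prob), si)
  tots <- as.numeric(rowsum(object$y, object$strata))
  out <- matrix(0L, length(prob), nsim)
  for (k in seq_along(idx)) {
    i <- idx[[k]]
    out[i, ] <- rmultinom(nsim, tots[k], prob[i])
  }
  as.data.frame(out)
}

#' @export
plot.ccpois <- function(x, ...) {
  plot(x$fitted.values, residuals(x, "pearson"),
       xlab = "fitted conditional mean", ylab = "Pearson residual",
       main = "Conditional quasi-Poisson residuals", ...)
  abline(h = 0, lty = 2)
  invisible(x)
}
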