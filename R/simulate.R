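#' Ground-truth parameters for the synthetic-data generator
#'
#' Collects every parameter the generator needs, with defaults
#' calibrated to the marginal summaries of the reference Toronto study:
#' daily medians near 16.1 ppb NO2, 31.5 ppb (max-8h) O3, 6.0 µg/m³
#' PM2.5, temperature quartiles near 1.7/18.4 °C, and about 20 ED visits
#' per day (83,985 visits over 4292 days).  Pollutant and temperature
#' series are seasonal Gaussian AR(1) processes; pollutants are clipped
#' at zero.  Counts follow a log-linear model with stratum-level
#' baseline variation, a single true exposure effect at a designated
#' lag, a smooth (quadratic) temperature effect, and negative-binomial
#' overdispersion with variance `phi * mean`.
#'
#' @param beta true log-RR per unit of the effect pollutant (default 0:
#'   null world).  For a target RR per IQR, set
#'   `beta = log(rr) / iqr` with the IQR of the simulated series.
#' @param effect_pollutant which pollutant drives the counts.
#' @param effect_lag lag (days) at which the effect acts.
#' @param base_rate expected daily count of visits.
#' @param stratum_sd standard deviation of the stratum-level
#'   log-baseline effects.
#' @param phi overdispersion factor (variance = `phi` * mean; 1 =
#'   Poisson).
#' @param temp_gamma curvature of the quadratic temperature effect
#'   `temp_gamma * ((temp - 12) / 10)^2` on the log scale.
#' @param series per-series parameters: a named list of lists with
#'   elements `level`, `amplitude`, `peak_doy`, `ar`, `sd`.
#' @return A list of class `"sim_truth"`.
#' @export
simulation_truth <- function(beta = 0, effect_pollutant = "pm25",
                             effect_lag = 1L, base_rate = 83985 / 4292,
                             stratum_sd = 0.05, phi = 1.3,
                             temp_gamma = 0.02,
                             series = NULL) {
  defaults <- list(
    no2  = list(level = 16.5, amplitude = 3.0, peak_doy = 15,  ar = 0.70, sd = 4.0),
    o3   = list(level = 31.5, amplitude = 8.0, peak_doy = 200, ar = 0.60, sd = 7.0),
    pm25 = list(level = 6.5,  amplitude = 1.5, peak_doy = 200, ar = 0.60, sd = 3.0),
    temp = list(level = 9.5,  amplitude = 12.0, peak_doy = 200, ar = 0.80, sd = 2.2)
  )
  if (!is.null(series)) {
    for (nm in names(series)) defaults[[nm]][names(series[[nm]])] <- series[[nm]]
  }
  stopifnot(base_rate > 0, phi >= 1, effect_lag >= 0)
  for (s in defaults) if (abs(s$ar) >= 1) stop("AR(1) coefficient must be in (-1, 1)")
  structure(list(beta = beta, effect_pollutant = effect_pollutant,
                 effect_lag = as.integer(effect_lag), base_rate = base_rate,
                 stratum_sd = stratum_sd, phi = phi, temp_gamma = temp_gamma,
                 series = defaults),
            class = "sim_truth")
}

## one seasonal AR(1) series (stationary start), optionally clipped at 0
.sim_series <- function(par, doy, clip0 = TRUE) {
  n <- length(doy)
  seasonal <- par$level + par$amplitude * cospi(2 * (doy - par$peak_doy) / 365.25)
  e <- numeric(n)
  e[1] <- rnorm(1, 0, par$sd / sqrt(1 - par$ar^2))
  innov <- rnorm(n - 1, 0, par$sd)
  for (t in 2:n) e[t] <- par$ar * e[t - 1] + innov[t - 1]
  x <- seasonal + e
  if (clip0) x[x < 0] <- 0
  x
}

#' Simulate daily exposure and temperature series
#'
#' Generates seasonal, autocorrelated, non-negative daily series for
#' NO2, O3, PM2.5 and temperature, plus the AQHI computed from the
#' three pollutants.  Draws come from R's active RNG stream: call
#' `set.seed()` first for reproducibility.
#'
#' @param n_days number of days.
#' @param truth a `"sim_truth"` object.
#' @param start first date of the series.
#' @return Daily exposure data frame with columns
#'   `date, no2, o3, pm25, temp, aqhi`.
#' @export
simulate_exposures <- function(n_days = 4292, truth = simulation_truth(),
                               start = "2004-04-01") {
  stopifnot(inherits(truth, "sim_truth"), n_days >= 1)
  dates <- seq(as.Date(start), by = "day", length.out = n_days)
  doy <- as.integer(format(dates, "%j"))
  out <- data.frame(
    date = dates,
    no2 = .sim_series(truth$series$no2, doy),
    o3 = .sim_series(truth$series$o3, doy),
    pm25 = .sim_series(truth$series$pm25, doy),
    temp = .sim_series(truth$series$temp, doy, clip0 = FALSE)
  )
  out$aqhi <- compute_aqhi(out$no2, out$o3, out$pm25)
  out
}

#' Disaggregate a daily series into an hourly multi-monitor panel
#'
#' Spreads each daily value over 24 hours with a smooth diurnal profile
#' and adds independent monitor noise, for exercising the hourly-to-
#' daily exposure metrics.  The monitor-and-hour mean of each day is
#' centred on the daily value.
#'
#' @param daily data frame with columns `date` and `value`.
#' @param n_monitors number of monitors (default 7).
#' @param diurnal_amplitude amplitude of the within-day cycle, as a
#'   fraction of the daily value.
#' @param monitor_sd standard deviation of monitor-level noise.
#' @return Hourly panel with columns `date, hour, monitor_id, value`.
#' @export
simulate_hourly_panel <- function(daily, n_monitors = 7,
                                  diurnal_amplitude = 0.2, monitor_sd = 1) {
  stopifnot(all(c("date", "value") %in% names(daily)))
  grid <- expand.grid(hour = 0:23, monitor_id = sprintf("S%02d", seq_len(n_monitors)),
                      date = as.Date(daily$date), stringsAsFactors = FALSE)
  base <- daily$value[match(grid$date, as.Date(daily$date))]
  cyc <- 1 + diurnal_amplitude * cospi(2 * (grid$hour - 15) / 24)
  val <- base * cyc + rnorm(nrow(grid), 0, monitor_sd)
  grid$value <- pmax(val, 0)
  grid[c("date", "hour", "monitor_id", "value")]
}

#' Simulate daily ED-visit counts with known ground truth
#'
#' Draws daily counts from the log-linear model the analysis assumes:
#' `log mu_d = alpha_strat(d) + beta * AP_(d - lag) + f(temp_(d - lag))`
#' with stratum effects `alpha ~ N(0, stratum_sd)`, the smooth
#' temperature effect of [simulation_truth()], and negative-binomial
#' dispersion `phi` (variance `phi * mu`; Poisson when `phi = 1`).  The
#' exposure and temperature terms are mean-centred and the series is
#' normalised so the average of `mu` equals `base_rate`.  Days whose
#' lagged exposure is undefined (the first `effect_lag` days) carry no
#' exposure contribution.
#'
#' @param exposures daily exposure table from [simulate_exposures()].
#' @param truth a `"sim_truth"` object.
#' @param subgroups if `TRUE`, split each day's total multinomially
#'   into the 42 sex x age x category cells with shares proportional to
#'   the reference study totals; if `FALSE` (default) return one row
#'   per day with all-patient counts.
#' @return A visit-count table (columns `date, sex, age_group,
#'   category, count`) with the true expected values in
#'   `attr(, "mu")`.
#' @export
simulate_counts <- function(exposures, truth = simulation_truth(),
                            subgroups = FALSE) {
  stopifnot(inherits(truth, "sim_truth"))
  dates <- as.Date(exposures$date)
  n <- length(dates)
  strat <- stratum_labels(dates)
  alpha <- rnorm(length(unique(strat)), 0, truth$stratum_sd)
  names(alpha) <- unique(strat)

  ap <- lag_series(exposures[[truth$effect_pollutant]], truth$effect_lag)
  tl <- lag_series(exposures$temp, truth$effect_lag)
  ap_c <- ifelse(is.na(ap), 0, ap - mean(ap, na.rm = TRUE))
  ftemp <- truth$temp_gamma * ((tl - 12) / 10)^2
  ftemp <- ifelse(is.na(ftemp), 0, ftemp - mean(ftemp, na.rm = TRUE))

  eta <- alpha[strat] + truth$beta * ap_c + ftemp
  mu <- truth$base_rate * exp(eta) / mean(exp(eta))
  y <- if (truth$phi <= 1) rpois(n, mu) else
    rnbinom(n, size = mu / (truth$phi - 1), mu = mu)

  if (!subgroups) {
    out <- data.frame(date = dates, sex = "all", age_group = "all",
                      category = "all", count = y)
  } else {
    ref <- toronto_visit_totals()
    share <- ref$count / sum(ref$count)
    cells <- t(vapply(y, function(tot)
      drop(rmultinom(1, tot, share)), integer(nrow(ref))))
    out <- data.frame(
      date = rep(dates, each = nrow(ref)),
      sex = rep(ref$sex, n),
      age_group = rep(ref$age_group, n),
      category = rep(ref$category, n),
      count = as.integer(t(cells))
    )
  }
  attr(out, "mu") <- mu
  out
}
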