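#' Daily mean concentration across monitors
#'
#' Collapses an hourly multi-monitor panel for one pollutant to a daily
#' series: first the mean across monitors reporting in each hour, then
#' the mean across hours of the day.  A day is reported only if at least
#' `completeness` of its 24 hours have at least one monitor value;
#' otherwise it is missing.  Averaging across monitors before hours makes
#' the daily value robust to monitors with different missingness
#' patterns.
#'
#' @param panel data frame with columns `date`, `hour` (0–23),
#'   `monitor_id`, `value`; one pollutant per call.
#' @param completeness minimum fraction of the 24 hours that must be
#'   observed (default 0.75, i.e. 18 hours).
#' @return Data frame with columns `date` and `value` (`NA` where the
#'   completeness criterion fails), one row per date present in `panel`.
#' @export
daily_mean_across_monitors <- function(panel, completeness = 0.75) {
  stopifnot(all(c("date", "hour", "monitor_id", "value") %in% names(panel)))
  if (nrow(panel) == 0L) stop("empty hourly panel")
  if (any(panel$hour < 0 | panel$hour > 23)) stop("hour must be in 0..23")
  panel$date <- as.Date(panel$date)
  ok <- !is.na(panel$value)
  hourly <- aggregate(list(value = panel$value[ok]),
                      by = list(date = panel$date[ok], hour = panel$hour[ok]),
                      FUN = mean)
  n_hours <- tapply(hourly$hour, hourly$date, length)
  day_mean <- tapply(hourly$value, hourly$date, mean)
  dates <- sort(unique(panel$date))
  value <- day_mean[as.character(dates)]
  nh <- n_hours[as.character(dates)]
  value[is.na(nh) | nh < completeness * 24] <- NA_real_
  data.frame(date = dates, value = as.numeric(value))
}

#' Daily maximum 8-hour mean
#'
#' The regulatory ozone metric: for each day, the maximum over the 17
#' same-day 8-hour windows (starting hours 0–16) of the window mean.  A
#' window counts only if at least `min_hours_in_window` of its 8 hours
#' are observed; a day with no valid window is missing.  Windows do not
#' cross midnight.
#'
#' @param hourly data frame with columns `date`, `hour`, `value`
#'   (already averaged across monitors, e.g. the hourly output of a
#'   single-monitor panel).
#' @param min_hours_in_window minimum observed hours per window
#'   (default 6).
#' @return Data frame with columns `date` and `value`.
#' @export
daily_max_8h <- function(hourly, min_hours_in_window = 6L) {
  stopifnot(all(c("date", "hour", "value") %in% names(hourly)))
  hourly$date <- as.Date(hourly$date)
  dates <- sort(unique(hourly$date))
  value <- vapply(dates, function(d) {
    v <- rep(NA_real_, 24L)
    sel <- hourly$date == d
    v[hourly$hour[sel] + 1L] <- hourly$value[sel]
    best <- -Inf
    for (s in 1:17) {
      w <- v[s:(s + 7L)]
      if (sum(!is.na(w)) >= min_hours_in_window)
        best <- max(best, mean(w, na.rm = TRUE))
    }
    if (is.finite(best)) best else NA_real_
  }, numeric(1))
  data.frame(date = dates, value = value)
}

#' Air Quality Health Index
#'
#' Canada's AQHI combines NO2, O3 and PM2.5 through the fixed
#' exponential excess-risk formula
#' \deqn{AQHI = \frac{1000}{10.4}\left(e^{0.000871\,NO_2} +
#'   e^{0.000537\,O_3} + e^{0.000487\,PM_{2.5}} - 3\right)}
#' with NO2 and O3 in ppb and PM2.5 in µg/m³.  The coefficients come
#' from a multi-city Canadian time-series study of air pollution and
#' mortality and are fixed constants, not tunable parameters.  The index
#' is 0 when all three inputs are 0 and strictly increasing in each;
#' missing inputs propagate to a missing index.
#'
#' @param no2 nitrogen dioxide, ppb.
#' @param o3 ozone (daily maximum 8-h mean), ppb.
#' @param pm25 fine particulate matter, µg/m³.
#' @return Numeric vector of AQHI values (unrounded).
#' @examples
#' compute_aqhi(16.1, 31.5, 6.0)  # about 3.28
#' @export
compute_aqhi <- function(no2, o3, pm25) {
  if (any(no2 < 0 | o3 < 0 | pm25 < 0, na.rm = TRUE))
    stop("concentrations must be non-negative")
  # expm1 keeps the near-zero branch exact: AQHI(0,0,0) is exactly 0
  (1000 / 10.4) * (expm1(0.000871 * no2) + expm1(0.000537 * o3) +
                     expm1(0.000487 * pm25))
}

#' Lag a daily series
#'
#' The lag-`k` value on day `d` is the input value on day `d - k`; the
#' first `k` days are missing and lag 0 is the identity.
#'
#' @param x numeric vector ordered by date (one value per consecutive
#'   day).
#' @param k non-negative integer lag, in days.
#' @return Numeric vector, same length as `x`.
#' @export
lag_series <- function(x, k) {
  k <- as.integer(k)
  if (is.na(k) || k < 0) stop("lag must be a non-negative integer")
  if (k == 0L) return(x)
  n <- length(x)
  if (k >= n) return(x[rep(NA_integer_, n)])
  c(x[rep(NA_integer_, k)], x[seq_len(n - k)])
}

#' Interquartile range of a daily series
#'
#' The RR scaling constant: Q3 minus Q1 over the analysis period, using
#' linear interpolation between order statistics (the "type 7" quantile
#' definition, R's default).  The quantile convention is recorded in the
#' result because published IQRs computed under other conventions can
#' differ in the last digit.
#'
#' @param x numeric vector (missing values dropped).
#' @param pollutant optional label carried along in the result.
#' @return A list of class `"scaling_spec"` with elements `pollutant`,
#'   `iqr` and `quantile_method`.
#' @export
iqr_spec <- function(x, pollutant = NA_character_) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) stop("need at least 2 non-missing values")
  q <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  structure(list(pollutant = pollutant, iqr = q[2] - q[1],
                 quantile_method = "type7"),
            class = "scaling_spec")
}

#' @export
print.scaling_spec <- function(x, ...) {
  cat(sprintf("IQR scaling: %s = %g (quantiles: %s)\n",
              if (is.na(x$pollutant)) "exposure" else x$pollutant,
              x$iqr, x$quantile_method))
  invisible(x)
}

#' Add lagged exposure and temperature columns to a daily table
#'
#' For each pollutant and lag, appends columns named
#' `<pollutant>_lag<k>` and `temp_lag<k>`.  Temperature is lagged by the
#' same number of days as the pollutant so that each model adjusts for
#' the temperature of the exposure day.
#'
#' @param exposures daily exposure data frame (see [read_exposures()]).
#' @param pollutants exposure columns to lag.
#' @param lags integer lags in days.
#' @return The input data frame with the lag columns appended.
#' @export
add_lags <- function(exposures, pollutants = c("no2", "o3", "pm25"),
                     lags = 0:5) {
  stopifnot(all(pollutants %in% names(exposures)), "temp" %in% names(exposures))
  exposures <- exposures[order(as.Date(exposures$date)), , drop = FALSE]
  for (k in lags) {
    for (p in pollutants)
      exposures[[sprintf("%s_lag%d", p, k)]] <- lag_series(exposures[[p]], k)
    exposures[[sprintf("temp_lag%d", k)]] <- lag_series(exposures$temp, k)
  }
  exposures
}
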