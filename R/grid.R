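.match_dim <- function(values, sel) {
  if (identical(sel, "all")) rep(TRUE, length(values)) else values == sel
}

.subgroup_label <- function(sex, age_group, category) {
  s <- c(all = "A", M = "M", F = "F")[[sex]]
  lab <- s
  if (age_group != "all") lab <- sprintf("%s[%s]", lab, age_group)
  if (category != "all") lab <- sprintf("%s:%s", lab, category)
  lab
}

#' Daily counts for one subgroup
#'
#' Sums the visit-count table over the rows matching a subgroup selector
#' and returns one count per requested date, filling days with no
#' matching visits with a true zero.  Aggregating counts before fitting
#' (rather than pooling subgroup-level estimates) is how the "all
#' patients" analyses are defined.
#'
#' @param counts visit-count table (see [read_visit_counts()]).
#' @param dates vector of dates the series must cover.
#' @param sex,age_group,category selectors; `"all"` means no restriction.
#' @return Data frame with columns `date` and `count`.
#' @export
subgroup_counts <- function(counts, dates, sex = "all", age_group = "all",
                            category = "all") {
  sel <- .match_dim(counts$sex, sex) &
    .match_dim(counts$age_group, age_group) &
    .match_dim(counts$category, category)
  dates <- as.Date(dates)
  out <- data.frame(date = dates, count = 0L)
  if (any(sel)) {
    agg <- aggregate(list(count = counts$count[sel]),
                     by = list(date = as.Date(counts$date)[sel]), FUN = sum)
    m <- match(dates, agg$date)
    out$count[!is.na(m)] <- agg$count[m[!is.na(m)]]
  }
  out
}

#' Assemble the analysis dataset for one grid cell
#'
#' Joins the subgroup's daily counts with the chosen pollutant at the
#' chosen lag, the temperature at the same lag, and the time-stratified
#' stratum label of the outcome day.  Rows with a missing exposure or
#' temperature are excluded at fit time.
#'
#' @param counts visit-count table.
#' @param exposures daily exposure table with a `temp` column.
#' @param pollutant exposure column name (e.g. `"no2"`, `"aqhi"`).
#' @param lag non-negative integer lag in days.
#' @inheritParams subgroup_counts
#' @return Data frame with columns `date`, `count`, `exposure`, `temp`,
#'   `stratum`.
#' @export
prepare_analysis <- function(counts, exposures, pollutant, lag = 0L,
                             sex = "all", age_group = "all", category = "all") {
  stopifnot(pollutant %in% names(exposures), "temp" %in% names(exposures))
  exposures <- exposures[order(as.Date(exposures$date)), , drop = FALSE]
  dates <- as.Date(exposures$date)
  cc <- subgroup_counts(counts, dates, sex, age_group, category)
  data.frame(
    date = dates,
    count = cc$count,
    exposure = lag_series(exposures[[pollutant]], lag),
    temp = lag_series(exposures$temp, lag),
    stratum = stratum_labels(dates)
  )
}

#' Default subgroup grid
#'
#' The subgroups of the reference analysis: all patients, each sex, each
#' sex by age group, and each of the seven disorder categories for all
#' patients, males and females.
#'
#' @return Data frame with columns `sex`, `age_group`, `category`
#'   (entries `"all"` meaning no restriction).
#' @export
default_subgroups <- function() {
  ages <- c("8-12", "13-18", "19-24")
  rbind(
    expand.grid(sex = c("all", "M", "F"), age_group = "all",
                category = "all", stringsAsFactors = FALSE),
    expand.grid(sex = c("all", "M", "F"), age_group = ages,
                category = "all", stringsAsFactors = FALSE),
    expand.grid(sex = c("all", "M", "F"), age_group = "all",
                category = disorder_categories(), stringsAsFactors = FALSE)
  )
}

#' Run the full subgroup x pollutant x lag analysis grid
#'
#' Fits one conditional quasi-Poisson model per grid cell and reports
#' the RR per interquartile range with its 95% confidence interval.
#' The IQR of each pollutant is computed once from its (unlagged) daily
#' series over the analysis period, so every lag of the same pollutant
#' is reported on the same scale.  Cells whose fit fails (e.g. a
#' subgroup with no visits, or an inestimable slope) appear in the
#' output with missing estimates and the failure reason in `note`.
#' No multiple-testing adjustment is applied across the grid: every
#' cell carries its own unadjusted 95% interval.
#'
#' @param counts visit-count table.
#' @param exposures daily exposure table.
#' @param subgroups data frame of subgroup selectors
#'   (default [default_subgroups()]).
#' @param pollutants exposure columns to analyse.
#' @param lags integer lags in days (default 0–5).
#' @param spline_df degrees of freedom of the temperature spline.
#' @return A data frame of class `"cc_grid"`, one row per cell, with
#'   columns `subgroup, sex, age_group, category, pollutant, lag, beta,
#'   se_beta, p, rr, rr_low, rr_high, n_days, n_strata, phi, note`; the
#'   per-pollutant IQRs are in `attr(, "iqr")`.
#' @export
run_grid <- function(counts, exposures, subgroups = default_subgroups(),
                     pollutants = c("no2", "o3", "pm25"), lags = 0:5,
                     spline_df = 3L) {
  stopifnot(nrow(subgroups) > 0, length(pollutants) > 0, length(lags) > 0)
  iqrs <- vapply(pollutants, function(p) iqr_spec(exposures[[p]], p)$iqr,
                 numeric(1))
  dates <- as.Date(exposures$date)

  rows <- vector("list", nrow(subgroups) * length(pollutants) * length(lags))
  r <- 0L
  for (g in seq_len(nrow(subgroups))) {
    sx <- subgroups$sex[g]; ag <- subgroups$age_group[g]
    ct <- subgroups$category[g]
    cc <- subgroup_counts(counts, dates, sx, ag, ct)
    for (p in pollutants) {
      for (k in lags) {
        r <- r + 1L
        d <- data.frame(
          count = cc$count,
          exposure = lag_series(exposures[[p]], k),
          temp = lag_series(exposures$temp, k),
          stratum = stratum_labels(dates)
        )
        base <- data.frame(
          subgroup = .subgroup_label(sx, ag, ct), sex = sx, age_group = ag,
          category = ct, pollutant = p, lag = as.integer(k),
          beta = NA_real_, se_beta = NA_real_, p = NA_real_,
          rr = NA_real_, rr_low = NA_real_, rr_high = NA_real_,
          n_days = NA_integer_, n_strata = NA_integer_, phi = NA_real_,
          note = "", stringsAsFactors = FALSE
        )
        rows[[r]] <- tryCatch({
          if (sum(d$count) == 0) stop("subgroup has zero counts on every day")
          fit <- ccpois(count ~ exposure + nsb(temp, spline_df), d,
                        strata = stratum)
          est <- rr_per_iqr(fit, iqrs[[p]])
          base$beta <- est$beta; base$se_beta <- est$se_beta
          base$p <- est$p; base$rr <- est$rr
          base$rr_low <- est$rr_low; base$rr_high <- est$rr_high
          base$n_days <- fit$n; base$n_strata <- fit$n_strata
          base$phi <- fit$dispersion
          if (!fit$converged) base$note <- "not converged"
          base
        }, error = function(e) {
          base$note <- conditionMessage(e)
          base
        })
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "iqr") <- iqrs
  class(out) <- c("cc_grid", class(out))
  out
}

#' @export
print.cc_grid <- function(x, ...) {
  ok <- !is.na(x$rr)
  cat(sprintf("cc_grid: %d cells (%d fitted, %d failed); %d significant (rr_low > 1)\n",
              nrow(x), sum(ok), sum(!ok), sum(x$rr_low > 1, na.rm = TRUE)))
  NextMethod()
}

#' Significance map of a results grid
#'
#' The qualitative map of the grid: entry 1 where the RR per IQR is
#' positively statistically significant — the lower 95% confidence limit
#' strictly above 1 — and 0 otherwise (including failed cells).
#'
#' @param grid a `"cc_grid"` from [run_grid()].
#' @return A 0/1 matrix of class `"cc_sigmap"`, rows indexed by
#'   `subgroup.pollutant`, columns by lag.
#' @export
significance_map <- function(grid) {
  stopifnot(inherits(grid, "cc_grid") || is.data.frame(grid))
  flag <- as.integer(!is.na(grid$rr_low) & grid$rr_low > 1)
  key <- paste(grid$subgroup, grid$pollutant, sep = ".")
  lags <- sort(unique(grid$lag))
  rows <- unique(key)
  m <- matrix(0L, length(rows), length(lags),
              dimnames = list(rows, paste0("lag", lags)))
  m[cbind(match(key, rows), match(grid$lag, lags))] <- flag
  structure(m, class = c("cc_sigmap", "matrix"))
}

#' @export
plot.cc_sigmap <- function(x, ...) {
  m <- unclass(x)
  op <- par(mar = c(4, 8, 2, 1)); on.exit(par(op))
  image(seq_len(ncol(m)), seq_len(nrow(m)), t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
        col = c("white", "red"), zlim = c(0, 1), axes = FALSE,
        xlab = "lag (days)", ylab = "",
        main = "Positive statistically significant associations")
  axis(1, at = seq_len(ncol(m)), labels = sub("lag", "", colnames(m)))
  axis(2, at = seq_len(nrow(m)), labels = rev(rownames(m)), las = 2, cex.axis = 0.6)
  invisible(x)
}

#' Period-split sensitivity analysis
#'
#' Halves the study period at a cutpoint, rebuilds the time-stratified
#' strata independently within each interval (strata are
#' calendar-defined, so none spans the cut) and reruns the identical
#' grid on both halves.
#'
#' @param counts visit-count table.
#' @param exposures daily exposure table.
#' @param cutpoint last day of the first interval
#'   (default `"2009-12-31"`, splitting April 2004–December 2009 from
#'   January 2010 onwards).
#' @param ... passed on to [run_grid()].
#' @return A list of class `"cc_split"` with elements `first`, `second`
#'   (two `"cc_grid"`s) and `comparison` (paired estimates side by side).
#' @export
sensitivity_split <- function(counts, exposures, cutpoint = "2009-12-31", ...) {
  cutpoint <- as.Date(cutpoint)
  dates <- as.Date(exposures$date)
  if (cutpoint < min(dates) || cutpoint >= max(dates))
    stop("cutpoint must fall inside the study period")
  e1 <- exposures[dates <= cutpoint, , drop = FALSE]
  e2 <- exposures[dates > cutpoint, , drop = FALSE]
  c1 <- counts[as.Date(counts$date) <= cutpoint, , drop = FALSE]
  c2 <- counts[as.Date(counts$date) > cutpoint, , drop = FALSE]
  g1 <- run_grid(c1, e1, ...)
  g2 <- run_grid(c2, e2, ...)
  keys <- c("subgroup", "sex", "age_group", "category", "pollutant", "lag")
  vals <- c("beta", "se_beta", "rr", "rr_low", "rr_high")
  comparison <- merge(g1[c(keys, vals)], g2[c(keys, vals)],
                      by = keys, suffixes = c("_1", "_2"))
  structure(list(first = g1, second = g2, comparison = comparison,
                 cutpoint = cutpoint),
            class = "cc_split")
}

#' @export
print.cc_split <- function(x, ...) {
  cat(sprintf("Period-split sensitivity at %s: %d paired cells\n",
              format(x$cutpoint), nrow(x$comparison)))
  invisible(x)
}

#' Multi-pollutant sensitivity analysis via the AQHI
#'
#' Reruns the grid with the Air Quality Health Index as the exposure,
#' an amalgamated measure of NO2, O3 and PM2.5; the RR is scaled per
#' AQHI interquartile range.  If the exposure table has no `aqhi`
#' column it is computed from the three pollutant columns with
#' [compute_aqhi()].
#'
#' @param counts visit-count table.
#' @param exposures daily exposure table.
#' @param ... passed on to [run_grid()] (except `pollutants`).
#' @return A `"cc_grid"` with `pollutant == "aqhi"`.
#' @export
aqhi_sensitivity <- function(counts, exposures, ...) {
  if (!"aqhi" %in% names(exposures))
    exposures$aqhi <- compute_aqhi(exposures$no2, exposures$o3, exposures$pm25)
  run_grid(counts, exposures, pollutants = "aqhi", ...)
}

#' Write grid results in the conventional report layout
#'
#' Splits a results grid into the three conventional files:
#' `ResAll.csv` (all patients, males, females — no age or category
#' restriction), `ResAgeGSex.csv` (sex by age group) and
#' `ResTypeAMF.csv` (disorder category by all/male/female), plus the
#' 0/1 significance map in `SigMap.csv`.
#'
#' @param grid a `"cc_grid"`.
#' @param dir output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_result_files <- function(grid, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  f <- function(sel, name) {
    path <- file.path(dir, name)
    write.csv(grid[sel, , drop = FALSE], path, row.names = FALSE)
    path
  }
  paths <- c(
    f(grid$age_group == "all" & grid$category == "all", "ResAll.csv"),
    f(grid$age_group != "all" & grid$category == "all", "ResAgeGSex.csv"),
    f(grid$category != "all", "ResTypeAMF.csv")
  )
  sig <- significance_map(grid)
  sig_path <- file.path(dir, "SigMap.csv")
  write.csv(as.data.frame(unclass(sig)), sig_path, row.names = TRUE)
  invisible(c(paths, sig_path))
}
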