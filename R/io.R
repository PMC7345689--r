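#' Read a daily visit-count table
#'
#' Reads a long-format CSV of daily ED-visit counts with columns
#' `date,sex,age_group,category,count` (ISO-8601 dates).  If the file
#' carries an `icd10` column instead of `category`, codes are mapped to
#' the seven disorder categories via `map` and counts are summed within
#' category.  Duplicate `(date, sex, age_group, category)` keys are
#' summed; malformed dates or negative counts are rejected with the
#' offending row numbers.
#'
#' @param path path to a delimited text file with header.
#' @param map ICD-10 prefix map, used only when an `icd10` column is
#'   present; see [default_disorder_map()].
#' @return A data frame with columns `date` (`Date`), `sex`, `age_group`,
#'   `category`, `count` (integer), one row per key.
#' @export
read_visit_counts <- function(path, map = default_disorder_map()) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("date", "sex", "age_group", "count")
  if (!all(required %in% names(raw)))
    stop("visit-count file must have columns date, sex, age_group, count and either category or icd10")
  if (nrow(raw) == 0L) {
    warning("empty visit-count file: ", path)
    return(data.frame(date = as.Date(character()), sex = character(),
                      age_group = character(), category = character(),
                      count = integer()))
  }
  if ("icd10" %in% names(raw) && !"category" %in% names(raw))
    raw$category <- map_icd10(raw$icd10, map)
  if (!"category" %in% names(raw))
    stop("visit-count file must have a 'category' or 'icd10' column")

  date <- as.Date(raw$date, format = "%Y-%m-%d")
  if (anyNA(date))
    stop("malformed date(s) at row(s): ",
         paste(which(is.na(date)), collapse = ", "))
  count <- suppressWarnings(as.numeric(raw$count))
  bad <- is.na(count) | count < 0 | count != round(count)
  if (any(bad))
    stop("negative, non-integer or missing count(s) at row(s): ",
         paste(which(bad), collapse = ", "))

  out <- aggregate(list(count = as.integer(count)),
                   by = list(date = date, sex = raw$sex,
                             age_group = raw$age_group,
                             category = raw$category),
                   FUN = sum)
  out <- out[order(out$date, out$sex, out$age_group, out$category), ]
  rownames(out) <- NULL
  out
}

#' Write a visit-count table
#'
#' Inverse of [read_visit_counts()]: writes the long-format CSV with
#' ISO-8601 dates so that a write/read round trip reproduces the table.
#'
#' @param x visit-count data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_visit_counts <- function(x, path) {
  stopifnot(all(c("date", "sex", "age_group", "category", "count") %in% names(x)))
  out <- x[, c("date", "sex", "age_group", "category", "count")]
  out$date <- format(as.Date(out$date), "%Y-%m-%d")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Aggregate visit counts over chosen dimensions
#'
#' Marginal sums of a count table over any subset of its key columns.
#' With `by = NULL` the grand total is returned; marginals over any
#' partition of the dimensions conserve the grand total.
#'
#' @param x data frame with a `count` column.
#' @param by character vector of grouping columns, or `NULL` for the
#'   grand total.
#' @return A data frame of group sums, or a single number when
#'   `by = NULL`.
#' @export
aggregate_totals <- function(x, by = NULL) {
  stopifnot("count" %in% names(x))
  if (is.null(by) || length(by) == 0L) return(sum(x$count))
  missing_keys <- setdiff(by, names(x))
  if (length(missing_keys))
    stop("unknown grouping column(s): ", paste(missing_keys, collapse = ", "))
  out <- aggregate(list(count = x$count), by = x[by], FUN = sum)
  out <- out[do.call(order, out[by]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read or write a daily exposure table
#'
#' Daily exposure CSVs have columns
#' `date,no2,o3,pm25,temp` and optionally `aqhi`; `no2` and `o3` are in
#' ppb (`o3` the daily maximum 8-h mean), `pm25` in µg/m³, `temp` in °C.
#'
#' @param path file path.
#' @return `read_exposures()`: a data frame with a `Date` column `date`;
#'   `write_exposures()`: `path`, invisibly.
#' @export
read_exposures <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("date", "no2", "o3", "pm25", "temp") %in% names(x)))
  x$date <- as.Date(x$date)
  if (anyNA(x$date)) stop("malformed date(s) in exposure file")
  if (anyDuplicated(x$date)) stop("duplicate dates in exposure file")
  x[order(x$date), , drop = FALSE]
}

#' @rdname read_exposures
#' @param x daily exposure data frame.
#' @export
write_exposures <- function(x, path) {
  x$date <- format(as.Date(x$date), "%Y-%m-%d")
  write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' Collects the settings a full analysis run depends on.  Defaults follow
#' the package's reference study: period April 2004 to December 2015,
#' lags 0–5 days, temperature splines with 3 degrees of freedom.
#'
#' @param study_start,study_end study period endpoints.
#' @param lags non-negative integer exposure lags, in days.
#' @param pollutants exposure columns to analyse.
#' @param spline_df degrees of freedom of the natural-spline temperature
#'   adjustment.
#' @param rng_seed integer seed for simulation.
#' @return A list of class `"cc_config"`.
#' @export
cc_config <- function(study_start = "2004-04-01", study_end = "2015-12-31",
                      lags = 0:5, pollutants = c("no2", "o3", "pm25"),
                      spline_df = 3L, rng_seed = 1L) {
  study_start <- as.Date(study_start)
  study_end <- as.Date(study_end)
  if (study_start >= study_end) stop("study_start must precede study_end")
  if (any(lags < 0)) stop("lags must be non-negative")
  if (spline_df < 1) stop("spline_df must be >= 1")
  structure(list(study_start = study_start, study_end = study_end,
                 lags = as.integer(lags), pollutants = pollutants,
                 spline_df = as.integer(spline_df),
                 rng_seed = as.integer(rng_seed)),
            class = "cc_config")
}

#' Read a run configuration from a JSON file
#'
#' Keys present in the file override the defaults of [cc_config()].
#'
#' @param path JSON file path.
#' @return A `"cc_config"` list.
#' @export
read_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(cc_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(cc_config, vals)
}
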