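#' Time-stratified stratum labels
#'
#' Assigns every date to its case-crossover stratum, defined by the
#' nested hierarchy year : month : day-of-week.  All days sharing those
#' three attributes form one stratum; in a complete calendar month every
#' stratum has 4 or 5 members depending on the month length.  Day-of-week
#' follows ISO numbering (Monday = 1).
#'
#' @param dates vector of dates (`Date` or ISO-8601 strings).
#' @return Character vector of stratum labels of the form
#'   `"YYYY-MM.w"` where `w` is the ISO weekday number.
#' @examples
#' stratum_labels(as.Date("2010-01-15"))  # "2010-01.5" (a Friday)
#' @export
stratum_labels <- function(dates) {
  dates <- as.Date(dates)
  lt <- as.POSIXlt(dates)
  isodow <- ifelse(lt$wday == 0L, 7L, lt$wday)
  sprintf("%04d-%02d.%d", lt$year + 1900L, lt$mon + 1L, isodow)
}

#' Build the stratum index for a set of study days
#'
#' Partitions unique dates into time-stratified strata and returns the
#' full index: one entry per stratum with its member dates.
#'
#' @param dates vector of unique dates.
#' @return A list of class `"stratum_index"`: named list of `Date`
#'   vectors (sorted members), names being the stratum labels.
#' @export
build_strata <- function(dates) {
  dates <- as.Date(dates)
  if (anyDuplicated(dates)) stop("dates must be unique")
  labels <- stratum_labels(dates)
  idx <- split(dates, labels)
  idx <- lapply(idx, sort)
  structure(idx[order(names(idx))], class = "stratum_index")
}

#' @export
print.stratum_index <- function(x, ...) {
  sizes <- lengths(x)
  cat(sprintf("stratum_index: %d days in %d strata (sizes %d-%d)\n",
              sum(sizes), length(x), min(sizes), max(sizes)))
  invisible(x)
}

#' Referent days of a case day
#'
#' The control (referent) days of a case day are the other members of
#' its stratum: the same weekdays of the same calendar month.  A date
#' whose stratum has shrunk to a singleton (e.g. after missing-exposure
#' exclusions) has an empty referent set and carries no conditional
#' information.
#'
#' @param date a single date.
#' @param index a `"stratum_index"` from [build_strata()].
#' @return `Date` vector of referent days (possibly empty).
#' @export
referent_set <- function(date, index) {
  date <- as.Date(date)
  stopifnot(length(date) == 1L, inherits(index, "stratum_index"))
  lab <- stratum_labels(date)
  members <- index[[lab]]
  if (is.null(members) || !date %in% members)
    stop("date ", format(date), " is not in the stratum index")
  members[members != date]
}
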