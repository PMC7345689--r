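#' Reference ED-visit totals by sex, age group and disorder category
#'
#' The published study-period totals of ED visits for mental disorders
#' among 8–24 year olds in Toronto, April 2004 – December 2015, in long
#' format: one row per (sex, age group, category) cell.  Useful as an
#' aggregation reference and to calibrate the synthetic generator's
#' subgroup shares (the grand total is 83,985 visits over 4292 days,
#' about 20 visits/day).
#'
#' @return Data frame with columns `sex`, `age_group`, `category`,
#'   `count` (42 rows).
#' @export
toronto_visit_totals <- function() {
  cats <- disorder_categories()
  cell <- function(sex, age, counts)
    data.frame(sex = sex, age_group = age, category = cats,
               count = as.integer(counts))
  rbind(
    cell("M", "8-12",  c(82, 11, 81, 185, 435, 23, 1110)),
    cell("M", "13-18", c(186, 3662, 1540, 2514, 1774, 178, 2051)),
    cell("M", "19-24", c(219, 8405, 7107, 4718, 4777, 444, 1674)),
    cell("F", "8-12",  c(44, 11, 93, 242, 492, 9, 526)),
    cell("F", "13-18", c(181, 3460, 1169, 4835, 3104, 438, 2722)),
    cell("F", "19-24", c(229, 6019, 3486, 6597, 6009, 1067, 2076))
  )
}
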