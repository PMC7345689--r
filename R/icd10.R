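#' The seven mental-disorder categories
#'
#' Canonical category labels, in the reporting order used throughout:
#' organic disorders, substance-related disorders, schizophrenic and
#' psychotic disorders, mood disorders, anxiety disorders, personality
#' disorders, and other.
#'
#' @return Character vector of length 7.
#' @export
disorder_categories <- function() {
  c("organic", "substance", "psychotic", "mood",
    "anxiety", "personality", "other")
}

#' Default ICD-10 code to disorder-category map
#'
#' Maps three-character ICD-10 code prefixes to the seven disorder
#' categories using the standard chapter blocks of the mental and
#' behavioural disorders chapter:
#' F00–F09 organic, F10–F19 substance-related, F20–F29 schizophrenic and
#' psychotic, F30–F39 mood, F40–F48 anxiety, F60–F69 personality, with
#' the remaining F-chapter blocks (F50–F59, F70–F99 and F49) and the
#' intentional self-harm codes X60–X84 assigned to "other".
#'
#' The map is an ordinary data frame (`icd10_prefix`, `category`) and can
#' be replaced wholesale by a user-supplied table with the same columns,
#' e.g. one read from a CSV file.
#'
#' @return A data frame with columns `icd10_prefix` and `category`.
#' @export
default_disorder_map <- function() {
  blk <- function(letter, from, to, category) {
    data.frame(icd10_prefix = sprintf("%s%02d", letter, from:to),
               category = category)
  }
  rbind(
    blk("F", 0, 9, "organic"),
    blk("F", 10, 19, "substance"),
    blk("F", 20, 29, "psychotic"),
    blk("F", 30, 39, "mood"),
    blk("F", 40, 48, "anxiety"),
    blk("F", 60, 69, "personality"),
    blk("F", 49, 49, "other"),
    blk("F", 50, 59, "other"),
    blk("F", 70, 99, "other"),
    blk("X", 60, 84, "other")
  )
}

#' Map ICD-10 codes to disorder categories
#'
#' Codes are matched by their first three characters against the prefix
#' table; codes with no matching prefix are routed to `"other"` with a
#' warning, so that no visit record is silently dropped.
#'
#' @param codes character vector of ICD-10 codes (e.g. `"F32.1"`).
#' @param map prefix table as returned by [default_disorder_map()].
#' @return Character vector of category labels, same length as `codes`.
#' @examples
#' map_icd10("F32.1")  # "mood"
#' @export
map_icd10 <- function(codes, map = default_disorder_map()) {
  stopifnot(is.data.frame(map), all(c("icd10_prefix", "category") %in% names(map)))
  if (anyDuplicated(map$icd10_prefix))
    stop("disorder map assigns some prefix more than one category")
  prefix <- toupper(substr(trimws(codes), 1L, 3L))
  idx <- match(prefix, map$icd10_prefix)
  out <- map$category[idx]
  if (anyNA(idx)) {
    warning(sum(is.na(idx)), " ICD-10 code(s) not in the map; assigned to 'other'")
    out[is.na(idx)] <- "other"
  }
  out
}
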