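#' The six T-lymphocyte subset analytes
#'
#' Registry of the measurands handled by the package: CD3+, CD3+CD4+ and
#' CD3+CD8+ T cells, each as a percentage of lymphocytes and as an absolute
#' count. Percentages are bounded to \[0, 100\]; counts are nonnegative
#' cells/µl from single-platform flow cytometry.
#'
#' @return A tibble with one row per analyte: `analyte` (stable code),
#'   `kind` (`"percentage"` or `"absolute_count"`), `units`, and a
#'   human-readable `label`.
#' @examples
#' ri_analytes()
#' @export
ri_analytes <- function() {
  tibble::tibble(
    analyte = c("cd3_pct", "cd4_pct", "cd8_pct",
                "cd3_count", "cd4_count", "cd8_count"),
    kind = rep(c("percentage", "absolute_count"), each = 3),
    units = rep(c("%", "cells/ul"), each = 3),
    label = c("CD3+ T cell (%)", "CD3+CD4+ T cell (%)", "CD3+CD8+ T cell (%)",
              "CD3+ T cell count (cells/ul)", "CD3+CD4+ T cell count (cells/ul)",
              "CD3+CD8+ T cell count (cells/ul)")
  )
}

#' @rdname ri_analytes
#' @param analyte Character vector of analyte codes.
#' @export
analyte_kind <- function(analyte) {
  reg <- ri_analytes()
  m <- match(analyte, reg$analyte)
  if (anyNA(m)) {
    stop("unknown analyte code(s): ",
         paste(unique(analyte[is.na(m)]), collapse = ", "), call. = FALSE)
  }
  reg$kind[m]
}

analyte_codes <- function() ri_analytes()$analyte

#' Valid value range of an analyte
#'
#' @param analyte A single analyte code.
#' @return Numeric length-2 vector `c(lower, upper)`; counts are unbounded
#'   above (`Inf`).
#' @keywords internal
analyte_range <- function(analyte) {
  if (analyte_kind(analyte) == "percentage") c(0, 100) else c(0, Inf)
}

#' Age bands used for stratification
#'
#' Closed integer age bands 14-30, 31-45, 46-60, 61-75, 76-100 years,
#' following the WHO / Chinese age-division conventions used for adult
#' immunophenotyping panels. Bands are disjoint and cover ages 14-100;
#' ages outside that range are excluded from interval estimation.
#'
#' @return A tibble with columns `band` (label such as `"14-30"`),
#'   `lo`, `hi` (inclusive integer bounds).
#' @examples
#' age_bands()
#' @export
age_bands <- function() {
  tibble::tibble(
    band = c("14-30", "31-45", "46-60", "61-75", "76-100"),
    lo = c(14L, 31L, 46L, 61L, 76L),
    hi = c(30L, 45L, 60L, 75L, 100L)
  )
}

#' Assign records to age/sex strata
#'
#' Maps integer ages to the closed bands of [age_bands()]. Ages below 14 or
#' above 100 yield `NA` (out of range for reference-interval estimation).
#'
#' @param sex Character vector, `"M"` or `"F"` (recycled against `age`).
#' @param age Integer vector of ages in years.
#' @return A tibble with columns `sex`, `age`, `band` (`NA` when out of
#'   range) and `stratum` (`"M 14-30"` style label, `NA` when out of range).
#' @examples
#' assign_stratum(c("M", "F", "M"), c(30, 31, 13))
#' @export
assign_stratum <- function(sex, age) {
  sex <- validate_sex(sex)
  stopifnot(is.numeric(age))
  n <- max(length(sex), length(age))
  sex <- rep_len(sex, n)
  age <- rep_len(age, n)
  bands <- age_bands()
  idx <- rep(NA_integer_, n)
  for (i in seq_len(nrow(bands))) {
    idx[!is.na(age) & age >= bands$lo[i] & age <= bands$hi[i]] <- i
  }
  band <- bands$band[idx]
  tibble::tibble(
    sex = sex, age = age, band = band,
    stratum = ifelse(is.na(band), NA_character_, paste(sex, band))
  )
}

validate_sex <- function(sex) {
  sex <- as.character(sex)
  up <- toupper(sex)
  up[up %in% c("MALE")] <- "M"
  up[up %in% c("FEMALE")] <- "F"
  bad <- !is.na(up) & !(up %in% c("M", "F"))
  if (any(bad)) {
    stop("sex must be 'M' or 'F'; got: ",
         paste(unique(sex[bad]), collapse = ", "), call. = FALSE)
  }
  up
}

band_midage <- function(band) {
  b <- age_bands()
  m <- match(band, b$band)
  (b$lo[m] + b$hi[m]) / 2
}
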