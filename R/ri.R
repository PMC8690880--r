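#' Nonparametric reference interval
#'
#' Estimates the central `coverage` interval (default 2.5th-97.5th
#' percentiles) by the CLSI-style rank method: the limits sit at ranks
#' r = p·(n + 1) on the sorted sample, with linear interpolation between
#' adjacent order statistics and ranks clamped to \[1, n\]; the median sits
#' at rank 0.5·(n + 1). Rank methods are affine-equivariant and commute
#' with monotone transforms, so limits computed on original-scale values
#' agree with back-transformed limits computed on the Box-Cox scale.
#'
#' CLSI recommends at least 120 observations for nonparametric limits; a
#' warning (not an error) is issued below that, and an error below 20.
#'
#' @param values Numeric vector.
#' @param coverage Central coverage in (0, 1); default 0.95.
#' @param min_n Hard minimum sample size (default 20).
#' @param warn_n Soft minimum (default 120).
#' @param boot Number of bootstrap resamples for 90% confidence intervals
#'   on each limit; 0 (default) skips them, as routine reporting does.
#' @param boot_seed Seed for the bootstrap stream (ignored when
#'   `boot = 0`).
#' @return A list of class `reference_interval`: `lower`, `median`,
#'   `upper`, `n`, `coverage`, `method = "nonparametric-rank"`; with
#'   `boot > 0` also `lower_ci` and `upper_ci` (length-2 vectors).
#' @examples
#' nonparametric_ri(1:119)
#' @export
nonparametric_ri <- function(values, coverage = 0.95, min_n = 20,
                             warn_n = 120, boot = 0, boot_seed = 1L) {
  values <- sort(values[!is.na(values)])
  n <- length(values)
  if (n < min_n) {
    stop("need at least ", min_n, " observations for nonparametric limits; ",
         "got ", n, call. = FALSE)
  }
  if (n < warn_n) {
    warning("n = ", n, " is below the recommended minimum of ", warn_n,
            " for nonparametric reference limits", call. = FALSE)
  }
  stopifnot(coverage > 0, coverage < 1)
  at_rank <- function(r) {
    r <- min(max(r, 1), n)
    f <- floor(r)
    if (f == r || f == n) values[f]
    else values[f] + (r - f) * (values[f + 1] - values[f])
  }
  alpha <- (1 - coverage) / 2
  out <- structure(list(lower = at_rank(alpha * (n + 1)),
                        median = at_rank(0.5 * (n + 1)),
                        upper = at_rank((1 - alpha) * (n + 1)),
                        n = n, coverage = coverage,
                        method = "nonparametric-rank"),
                   class = "reference_interval")
  if (boot > 0) {
    lims <- with_stream(boot_seed, vapply(seq_len(boot), function(i) {
      v <- sort(sample(values, n, replace = TRUE))
      at <- function(r) {
        r <- min(max(r, 1), n); f <- floor(r)
        if (f == r || f == n) v[f] else v[f] + (r - f) * (v[f + 1] - v[f])
      }
      c(at(alpha * (n + 1)), at((1 - alpha) * (n + 1)))
    }, numeric(2)))
    out$lower_ci <- unname(stats::quantile(lims[1, ], c(0.05, 0.95),
                                           type = 7))
    out$upper_ci <- unname(stats::quantile(lims[2, ], c(0.05, 0.95),
                                           type = 7))
  }
  out
}

#' @export
print.reference_interval <- function(x, ...) {
  cat(sprintf("%.0f%% reference interval (%s, n = %d): %.4g - %.4g (median %.4g)\n",
              100 * x$coverage, x$method, x$n, x$lower, x$upper, x$median))
  invisible(x)
}

#' Stratified reference intervals for a cohort
#'
#' Computes one nonparametric interval per analyte × stratum on the
#' original measurement scale, using only outlier-retained records, plus an
#' unstratified "all" interval per analyte. Strata with fewer than `min_n`
#' retained values for an analyte are omitted with a warning, which is why
#' per-analyte n differ.
#'
#' @param cohort A deduplicated `lis_cohort`.
#' @param retained Optional named list (by analyte) of row indices retained
#'   by [screen_analyte()]; defaults to all non-missing rows.
#' @param coverage Central coverage (default 0.95).
#' @param min_n,warn_n Passed to [nonparametric_ri()].
#' @param include_overall Add the per-analyte unstratified row (default
#'   TRUE).
#' @return A tibble: `analyte`, `sex`, `band`, `stratum`, `lower`,
#'   `median`, `upper`, `n`, `coverage`, `method`.
#' @export
estimate_reference_intervals <- function(cohort, retained = NULL,
                                         coverage = 0.95, min_n = 20,
                                         warn_n = 120,
                                         include_overall = TRUE) {
  cohort <- cohort_strata(cohort)
  rows <- list()
  emit <- function(analyte, sex, band, stratum, vals) {
    ri <- tryCatch(
      suppressWarnings(nonparametric_ri(vals, coverage, min_n, warn_n)),
      error = function(e) {
        warning("omitting ", analyte, " / ", stratum, ": ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
    if (is.null(ri)) return(invisible())
    rows[[length(rows) + 1]] <<- tibble::tibble(
      analyte = analyte, sex = sex, band = band, stratum = stratum,
      lower = ri$lower, median = ri$median, upper = ri$upper,
      n = ri$n, coverage = coverage, method = ri$method)
  }
  for (a in analyte_codes()) {
    keep <- retained[[a]] %||% which(!is.na(cohort[[a]]))
    sub <- cohort[keep, ]
    sub <- sub[!is.na(sub$stratum) & !is.na(sub[[a]]), ]
    for (s in unique(sub$stratum)) {
      g <- sub[sub$stratum == s, ]
      emit(a, g$sex[1], g$band[1], s, g[[a]])
    }
    if (include_overall) emit(a, NA_character_, NA_character_, "all", sub[[a]])
  }
  out <- dplyr::bind_rows(rows)
  out$sex_ord <- match(out$sex, c("M", "F"))
  out$band_ord <- match(out$band, age_bands()$band)
  out <- dplyr::arrange(out, match(.data$analyte, analyte_codes()),
                        .data$sex_ord, .data$band_ord)
  out$sex_ord <- out$band_ord <- NULL
  out
}
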