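#' Run the full indirect reference-interval pipeline
#'
#' Executes the four-step indirect method end to end on a cohort of LIS
#' records (or on a freshly generated synthetic cohort):
#' deduplication, skewness/kurtosis normality assessment, per-analyte
#' Box-Cox normalization with ML lambda, single-pass Tukey screening on the
#' transformed scale, Harris-Boyd partition scan over age/sex strata,
#' stratified nonparametric 95% limits with medians, group-difference
#' tests, age trends and the extreme-band decline statistics. The pipeline
#' is deterministic given the cohort (and, for synthetic input, the
#' [cohort_spec()] seed).
#'
#' @param cohort A `lis_cohort`; omit and pass `spec` to simulate instead.
#' @param spec A [cohort_spec()] used when `cohort` is NULL.
#' @param k Tukey fence multiplier (default 1.5).
#' @param coverage Interval coverage (default 0.95).
#' @param lambda_range Box-Cox search interval (default \[-3, 3\]).
#' @param z_crit Normality rule constant (default 1.96).
#' @param partition_mode `"adjacent"` or `"all-pairs"`.
#' @param sd_ratio_limit Harris-Boyd SD-ratio trigger; `Inf` disables.
#' @param min_n,warn_n Stratum size rules for [nonparametric_ri()].
#' @param out_dir Optional directory: the report tables are written as CSV
#'   plus a plain-text manifest.
#' @return A list of class `ri_report`: `normality`, `boxcox`, `screening`,
#'   `partition`, `intervals`, `medians`, `group_tests`, `trends`,
#'   `declines`, `counts`, `retained` (per-analyte row indices into the
#'   deduplicated cohort), `cohort` (deduplicated, stratified), `params`.
#' @examples
#' rep <- run_pipeline(spec = default_cohort_spec(n_per_stratum = 200,
#'                                                seed = 3))
#' rep$boxcox
#' @export
run_pipeline <- function(cohort = NULL, spec = NULL, k = 1.5,
                         coverage = 0.95, lambda_range = c(-3, 3),
                         z_crit = 1.96,
                         partition_mode = c("adjacent", "all-pairs"),
                         sd_ratio_limit = 1.5, min_n = 20, warn_n = 120,
                         out_dir = NULL) {
  partition_mode <- match.arg(partition_mode)
  if (is.null(cohort)) {
    if (is.null(spec)) stop("supply a cohort or a cohort_spec", call. = FALSE)
    cohort <- generate_cohort(spec)
  }
  n_input <- nrow(cohort)
  dd <- deduplicate(cohort)
  cohort <- cohort_strata(dd$cohort)

  normality <- list(); boxcox <- list(); screening <- list()
  partition <- list(); summaries <- list()
  retained <- stats::setNames(vector("list", 6), analyte_codes())
  transformed <- list()
  for (a in analyte_codes()) {
    vals <- cohort[[a]]
    idx <- which(!is.na(vals))
    fit <- fit_boxcox_mle(vals[idx], search_range = lambda_range,
                          z_crit = z_crit)
    y <- rep(NA_real_, nrow(cohort))
    y[idx] <- boxcox_transform(vals[idx], fit$lambda_hat)
    scr <- screen_analyte(y, k = k)
    retained[[a]] <- scr$retained
    transformed[[a]] <- y
    normality[[a]] <- tibble::tibble(
      analyte = a, n = fit$n,
      skewness_before = fit$before$skewness,
      kurtosis_before = fit$before$excess_kurtosis,
      z_skewness_before = fit$before$z_skewness,
      z_kurtosis_before = fit$before$z_kurtosis,
      normal_before = fit$before$is_normal,
      skewness_after = fit$after$skewness,
      kurtosis_after = fit$after$excess_kurtosis,
      z_skewness_after = fit$after$z_skewness,
      z_kurtosis_after = fit$after$z_kurtosis,
      normal_after = fit$after$is_normal)
    boxcox[[a]] <- tibble::tibble(
      analyte = a, lambda = fit$lambda_hat,
      log_likelihood = fit$log_likelihood,
      n = fit$n, n_outliers = scr$result$n_flagged,
      n_retained = scr$result$n_retained)
    screening[[a]] <- tibble::tibble(
      analyte = a, lambda = fit$lambda_hat, k = k,
      lower_fence_transformed = scr$result$lower_fence,
      upper_fence_transformed = scr$result$upper_fence,
      lower_fence_original = inverse_boxcox_clamped(scr$result$lower_fence,
                                                    fit$lambda_hat),
      upper_fence_original = inverse_boxcox_clamped(scr$result$upper_fence,
                                                    fit$lambda_hat),
      n_flagged = scr$result$n_flagged,
      n_retained = scr$result$n_retained)

    # transformed-scale, screened summaries feed the partition scan
    sub <- cohort[scr$retained, ]
    ysub <- y[scr$retained]
    keep <- !is.na(sub$stratum)
    summ <- dplyr::summarise(
      dplyr::group_by(tibble::tibble(sex = sub$sex[keep],
                                     band = sub$band[keep],
                                     y = ysub[keep]),
                      .data$sex, .data$band),
      n = dplyr::n(), mean = mean(.data$y), sd = stats::sd(.data$y),
      .groups = "drop")
    summaries[[a]] <- dplyr::mutate(summ, analyte = a, .before = 1)
    partition[[a]] <- partition_scan(summ, analyte = a,
                                     mode = partition_mode,
                                     sd_ratio_limit = sd_ratio_limit)
  }

  intervals <- estimate_reference_intervals(
    cohort, retained, coverage = coverage, min_n = min_n, warn_n = warn_n)
  medians <- intervals[intervals$stratum != "all",
                       c("analyte", "sex", "band", "median", "n")]

  group_tests <- dplyr::bind_rows(lapply(analyte_codes(), function(a) {
    tst <- tryCatch(group_difference_tests(cohort, a),
                    error = function(e) {
                      warning("group tests skipped for ", a, ": ",
                              conditionMessage(e), call. = FALSE)
                      NULL
                    })
    if (is.null(tst)) NULL else dplyr::mutate(tst, analyte = a, .before = 1)
  }))

  trends <- list(); declines <- list()
  young <- age_bands()$band[1]
  old <- age_bands()$band[nrow(age_bands())]
  for (a in analyte_codes()) {
    for (s in c("M", "F")) {
      tr <- tryCatch(age_trend(cohort, a, s), error = function(e) NULL)
      if (!is.null(tr)) {
        trends[[paste(a, s)]] <- tibble::tibble(
          analyte = a, sex = s, n = tr$n, correlation = tr$correlation,
          slope = tr$slope)
      }
      my <- medians$median[medians$analyte == a & medians$sex == s &
                             medians$band == young]
      mo <- medians$median[medians$analyte == a & medians$sex == s &
                             medians$band == old]
      if (length(my) == 1 && length(mo) == 1) {
        declines[[paste(a, s)]] <- tibble::tibble(
          analyte = a, sex = s, median_young = my, median_old = mo,
          decline = extreme_decline(my, mo, analyte_kind(a)))
      }
    }
  }

  report <- structure(list(
    normality = dplyr::bind_rows(normality),
    boxcox = dplyr::bind_rows(boxcox),
    screening = dplyr::bind_rows(screening),
    stratum_summaries = dplyr::bind_rows(summaries),
    partition = dplyr::bind_rows(partition),
    intervals = intervals,
    medians = medians,
    group_tests = group_tests,
    trends = dplyr::bind_rows(trends),
    declines = dplyr::bind_rows(declines),
    counts = tibble::tibble(
      n_input = n_input, n_duplicates_removed = dd$removed,
      n_deduplicated = nrow(cohort),
      n_out_of_age_range = attr(cohort, "n_out_of_range")),
    retained = retained,
    cohort = cohort,
    params = list(k = k, coverage = coverage, lambda_range = lambda_range,
                  z_crit = z_crit, partition_mode = partition_mode,
                  sd_ratio_limit = sd_ratio_limit, min_n = min_n,
                  warn_n = warn_n,
                  seed = attr(cohort, "seed"))
  ), class = "ri_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.ri_report <- function(x, ...) {
  cat("Indirect reference-interval report\n")
  cat(sprintf("  records: %d in, %d duplicates removed, %d analysed\n",
              x$counts$n_input, x$counts$n_duplicates_removed,
              x$counts$n_deduplicated))
  cat(sprintf("  intervals estimated: %d (incl. per-analyte overall)\n",
              nrow(x$intervals)))
  cat(sprintf("  partition comparisons requiring a split: %d of %d\n",
              sum(x$partition$partition_required), nrow(x$partition)))
  invisible(x)
}

#' Write a pipeline report bundle to disk
#'
#' Emits one CSV per table (normality, Box-Cox/outlier summary, screening
#' fences, partition decisions, intervals, medians, group tests, trends,
#' declines) plus `manifest.txt` echoing every parameter and count, so a
#' run can be reproduced from its manifest.
#'
#' @param report An `ri_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("normality", "boxcox", "screening", "partition", "intervals",
              "medians", "group_tests", "trends", "declines", "counts")
  for (t in tables) {
    utils::write.csv(as.data.frame(report[[t]]),
                     file.path(dir, paste0(t, ".csv")), row.names = FALSE)
  }
  p <- report$params
  lines <- c(
    "tcellri run manifest",
    paste0("package_version: ", as.character(utils::packageVersion("tcellri"))),
    paste0("seed: ", p$seed %||% "NA"),
    paste0("tukey_k: ", p$k),
    paste0("coverage: ", p$coverage),
    paste0("lambda_range: ", paste(p$lambda_range, collapse = " ")),
    paste0("normality_z_crit: ", p$z_crit),
    paste0("partition_mode: ", p$partition_mode),
    paste0("sd_ratio_limit: ", p$sd_ratio_limit),
    paste0("min_n: ", p$min_n),
    paste0("warn_n: ", p$warn_n),
    paste0("n_input: ", report$counts$n_input),
    paste0("n_duplicates_removed: ", report$counts$n_duplicates_removed),
    paste0("n_deduplicated: ", report$counts$n_deduplicated),
    paste0("n_out_of_age_range: ", report$counts$n_out_of_age_range))
  writeLines(lines, file.path(dir, "manifest.txt"))
  invisible(dir)
}
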