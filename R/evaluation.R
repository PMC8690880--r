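#' Verify a reference interval on an external cohort
#'
#' Counts validation values strictly below the lower or strictly above the
#' upper limit (boundary values are inside, matching the interval's
#' retained-boundary convention). The interval is verified when the outside
#' rate is strictly below `threshold` (default 5%); exactly 5% fails.
#'
#' @param ri A [nonparametric_ri()] result or any list with `lower` and
#'   `upper`.
#' @param validation_values Numeric vector, n >= 20.
#' @param threshold Verification threshold on the outside rate.
#' @return A list: `n_validation`, `n_outside`, `rate_outside`, `verified`.
#' @examples
#' validate_ri(list(lower = -1.96, upper = 1.96), rnorm(500))
#' @export
validate_ri <- function(ri, validation_values, threshold = 0.05) {
  v <- validation_values[!is.na(validation_values)]
  if (length(v) < 20) {
    stop("need at least 20 validation values; got ", length(v),
         call. = FALSE)
  }
  out <- sum(v < ri$lower | v > ri$upper)
  list(n_validation = length(v), n_outside = out,
       rate_outside = out / length(v),
       verified = out / length(v) < threshold)
}

#' Verify a stratified interval table on a validation cohort
#'
#' Applies [validate_ri()] stratum by stratum: each validation record is
#' judged by the interval of its own analyte × stratum. Strata present in
#' the cohort but absent from the table are listed in
#' `attr(, "missing_strata")`, not fatal.
#'
#' @param ri_table Output of [estimate_reference_intervals()].
#' @param cohort Validation `lis_cohort`.
#' @param threshold Verification threshold (default 0.05).
#' @return A tibble per analyte × stratum: `n_validation`, `n_outside`,
#'   `rate_outside`, `verified`, plus pooled per-analyte `"all"` rows using
#'   the stratified limits.
#' @export
verify_reference_intervals <- function(ri_table, cohort, threshold = 0.05) {
  cohort <- cohort_strata(cohort)
  rows <- list()
  missing_strata <- character(0)
  for (a in analyte_codes()) {
    tab <- ri_table[ri_table$analyte == a & ri_table$stratum != "all", ]
    pooled_out <- 0L; pooled_n <- 0L
    for (s in unique(cohort$stratum[!is.na(cohort$stratum)])) {
      vals <- cohort[[a]][!is.na(cohort$stratum) & cohort$stratum == s]
      vals <- vals[!is.na(vals)]
      if (!length(vals)) next
      row <- tab[tab$stratum == s, ]
      if (nrow(row) != 1) {
        missing_strata <- union(missing_strata, paste(a, s))
        next
      }
      rep <- tryCatch(validate_ri(row, vals, threshold),
                      error = function(e) NULL)
      if (is.null(rep)) next
      pooled_out <- pooled_out + rep$n_outside
      pooled_n <- pooled_n + rep$n_validation
      rows[[length(rows) + 1]] <- tibble::tibble(
        analyte = a, stratum = s, n_validation = rep$n_validation,
        n_outside = rep$n_outside, rate_outside = rep$rate_outside,
        verified = rep$verified)
    }
    if (pooled_n > 0) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        analyte = a, stratum = "all", n_validation = pooled_n,
        n_outside = pooled_out, rate_outside = pooled_out / pooled_n,
        verified = pooled_out / pooled_n < threshold)
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "missing_strata") <- missing_strata
  out
}

#' Compare two reference-interval sets on one validation cohort
#'
#' Judges every validation record against each interval set (a set may be
#' unstratified, like a reagent-manual interval: a single `"all"` row per
#' analyte) and tests the pooled 2x2 outside/inside × set contingency table
#' by chi-square, falling back to Fisher's exact test when any expected
#' count drops below 5. Symmetric in the two sets.
#'
#' @param ri_a,ri_b Interval tables as from
#'   [estimate_reference_intervals()].
#' @param cohort Validation `lis_cohort`.
#' @param labels Length-2 character labels for the sets.
#' @return A list: `counts` (2x2 matrix), `chi_square` (NA under the Fisher
#'   fallback), `p_value`, `test`, `per_analyte` breakdown tibble.
#' @export
compare_ri_sets <- function(ri_a, ri_b, cohort, labels = c("A", "B")) {
  cohort <- cohort_strata(cohort)
  judge <- function(tab) {
    out <- 0L; n <- 0L; per <- numeric(0)
    for (a in analyte_codes()) {
      rows <- tab[tab$analyte == a, ]
      if (!nrow(rows)) next
      vals <- cohort[[a]]
      strat <- cohort$stratum
      o <- 0L; m <- 0L
      for (i in seq_len(nrow(rows))) {
        r <- rows[i, ]
        sel <- if (r$stratum == "all" && !("all" %in% strat)) {
          # unstratified set: applies to every record not covered by a
          # stratified row of the same table
          if (any(rows$stratum != "all")) !is.na(vals) &
              !(strat %in% rows$stratum) else !is.na(vals)
        } else if (r$stratum == "all") !is.na(vals) else
          !is.na(vals) & !is.na(strat) & strat == r$stratum
        v <- vals[sel]
        o <- o + sum(v < r$lower | v > r$upper)
        m <- m + length(v)
      }
      out <- out + o; n <- n + m
      per[a] <- if (m > 0) o / m else NA_real_
    }
    list(out = out, n = n, per = per)
  }
  ja <- judge(ri_a); jb <- judge(ri_b)
  if (ja$n == 0 || jb$n == 0) {
    stop("no overlapping coverage between an interval set and the cohort",
         call. = FALSE)
  }
  counts <- matrix(c(ja$out, ja$n - ja$out, jb$out, jb$n - jb$out),
                   nrow = 2, byrow = TRUE,
                   dimnames = list(set = labels,
                                   judged = c("outside", "inside")))
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected < 5)) {
    ft <- stats::fisher.test(counts)
    res <- list(chi_square = NA_real_, p_value = ft$p.value,
                test = "fisher")
  } else {
    ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
    res <- list(chi_square = unname(ct$statistic), p_value = ct$p.value,
                test = "chi-square")
  }
  per <- tibble::tibble(
    analyte = union(names(ja$per), names(jb$per)),
    rate_a = ja$per[union(names(ja$per), names(jb$per))],
    rate_b = jb$per[union(names(ja$per), names(jb$per))])
  c(list(counts = counts), res, list(per_analyte = per))
}

#' Age- and sex-group difference tests
#'
#' Kruskal-Wallis across age bands within each sex and Mann-Whitney U
#' (two-sided Wilcoxon rank-sum) male vs female, on the original-scale
#' values of one analyte.
#'
#' @param cohort A `lis_cohort`.
#' @param analyte Analyte code.
#' @return A tibble: `test`, `scope`, `statistic`, `df`, `p_value`.
#' @export
group_difference_tests <- function(cohort, analyte) {
  cohort <- cohort_strata(cohort)
  ok <- !is.na(cohort[[analyte]]) & !is.na(cohort$stratum)
  df <- cohort[ok, ]
  if (!nrow(df)) stop("no usable records for ", analyte, call. = FALSE)
  rows <- list()
  for (s in intersect(c("M", "F"), unique(df$sex))) {
    g <- df[df$sex == s, ]
    sizes <- table(g$band)
    if (length(sizes) < 2 || any(sizes < 2)) {
      stop("degenerate age groups for sex ", s, call. = FALSE)
    }
    if (length(unique(g[[analyte]])) < 2) {
      stop("degenerate (constant) values for sex ", s, call. = FALSE)
    }
    kw <- stats::kruskal.test(g[[analyte]], factor(g$band))
    rows[[length(rows) + 1]] <- tibble::tibble(
      test = "kruskal-wallis", scope = paste("age bands,", s),
      statistic = unname(kw$statistic), df = unname(kw$parameter),
      p_value = kw$p.value)
  }
  if (all(c("M", "F") %in% df$sex)) {
    mw <- stats::wilcox.test(df[[analyte]][df$sex == "M"],
                             df[[analyte]][df$sex == "F"],
                             alternative = "two.sided", exact = FALSE)
    rows[[length(rows) + 1]] <- tibble::tibble(
      test = "mann-whitney", scope = "M vs F",
      statistic = unname(mw$statistic), df = NA_real_,
      p_value = mw$p.value)
  }
  dplyr::bind_rows(rows)
}

#' Age trend of an analyte within one sex
#'
#' Spearman rank correlation between value and age (Pearson available via
#' `method`), and the ordinary-least-squares slope of value on age in
#' analyte units per year.
#'
#' @param cohort A `lis_cohort`.
#' @param analyte Analyte code.
#' @param sex `"M"` or `"F"`.
#' @param method Correlation flavor, `"spearman"` (default) or
#'   `"pearson"`.
#' @return A list: `analyte`, `sex`, `n`, `correlation`, `slope`.
#' @export
age_trend <- function(cohort, analyte, sex,
                      method = c("spearman", "pearson")) {
  method <- match.arg(method)
  sex <- validate_sex(sex)
  sel <- cohort$sex == sex & !is.na(cohort[[analyte]]) & !is.na(cohort$age)
  v <- cohort[[analyte]][sel]
  a <- cohort$age[sel]
  if (length(v) < 30) {
    stop("need at least 30 records for sex ", sex, "; got ", length(v),
         call. = FALSE)
  }
  if (length(unique(v)) < 2) {
    warning("constant values: correlation undefined", call. = FALSE)
    return(list(analyte = analyte, sex = sex, n = length(v),
                correlation = NA_real_, slope = 0))
  }
  list(analyte = analyte, sex = sex, n = length(v),
       correlation = stats::cor(v, a, method = method),
       slope = unname(stats::coef(stats::lm(v ~ a))[2]))
}

#' Decline between the extreme age bands
#'
#' Summarizes immunosenescence as the drop in the stratum median from the
#' youngest to the oldest band. Conventions differ by analyte kind:
#' percentages decline in absolute percentage points
#' (`median_young − median_old`), already on a % scale, while absolute
#' counts decline relatively,
#' `100 · (median_young − median_old) / median_young` — both are reported
#' as "%". The dual convention is deliberate and is what published T-subset
#' decline figures use; see the methods vignette.
#'
#' @param median_young Median of the youngest band (14-30).
#' @param median_old Median of the oldest band (76-100).
#' @param kind `"percentage"` or `"absolute_count"`.
#' @return The decline (percentage points, or relative %).
#' @examples
#' extreme_decline(70.05, 60.10, "percentage")     # 9.95 points
#' extreme_decline(1309, 910, "absolute_count")    # 30.48 %
#' @export
extreme_decline <- function(median_young, median_old,
                            kind = c("percentage", "absolute_count")) {
  kind <- match.arg(kind)
  if (kind == "percentage") {
    median_young - median_old
  } else {
    if (any(median_young <= 0)) {
      stop("relative decline needs a positive young-band median",
           call. = FALSE)
    }
    100 * (median_young - median_old) / median_young
  }
}
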