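#' Summarize a stratum for partition testing
#'
#' @param values Numeric vector (transformed-scale, outlier-screened).
#' @param label Stratum identity.
#' @return A list with `label`, `n`, `mean`, `sd`.
#' @export
group_summary <- function(values, label = "") {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need n >= 2 per group", call. = FALSE)
  list(label = label, n = length(values),
       mean = mean(values), sd = stats::sd(values))
}

#' Harris-Boyd standard-normal-deviate partition test
#'
#' Decides whether two candidate subgroups need separate reference
#' intervals, using the CLSI EP28-A3C form of the Harris-Boyd test:
#' \deqn{z = \frac{\bar x_1 - \bar x_2}{\sqrt{s_1^2/n_1 + s_2^2/n_2}},
#'   \qquad z^* = 3\sqrt{\frac{(n_1+n_2)/2}{120}}.}
#' Partitioning is indicated when |z| exceeds z*. EP28-A3C's secondary
#' criterion — a larger-to-smaller SD ratio above `sd_ratio_limit` — is also
#' evaluated (set `sd_ratio_limit = Inf` to disable); the two triggers are
#' reported separately so the mean-based decision is auditable alone.
#'
#' @param group1,group2 [group_summary()] lists.
#' @param sd_ratio_limit SD-ratio trigger (default 1.5).
#' @return A list of class `partition_test`: the inputs plus `z`, `z_star`,
#'   `sd_ratio`, `mean_criterion`, `sd_criterion`, `partition_required`.
#' @examples
#' g1 <- list(label = "A", n = 120, mean = 0, sd = 1)
#' g2 <- list(label = "B", n = 120, mean = 1, sd = 1)
#' harris_boyd(g1, g2)
#' @export
harris_boyd <- function(group1, group2, sd_ratio_limit = 1.5) {
  for (g in list(group1, group2)) {
    if (g$n < 2) stop("need n >= 2 in both groups", call. = FALSE)
    if (!is.finite(g$sd) || g$sd <= 0) {
      stop("degenerate group '", g$label, "': zero or undefined SD",
           call. = FALSE)
    }
  }
  z <- (group1$mean - group2$mean) /
    sqrt(group1$sd^2 / group1$n + group2$sd^2 / group2$n)
  z_star <- 3 * sqrt(((group1$n + group2$n) / 2) / 120)
  sd_ratio <- max(group1$sd, group2$sd) / min(group1$sd, group2$sd)
  mean_crit <- abs(z) > z_star
  sd_crit <- is.finite(sd_ratio_limit) && sd_ratio > sd_ratio_limit
  structure(list(group1 = group1, group2 = group2,
                 z = z, z_star = z_star, sd_ratio = sd_ratio,
                 mean_criterion = mean_crit, sd_criterion = sd_crit,
                 partition_required = mean_crit || sd_crit),
            class = "partition_test")
}

#' @export
print.partition_test <- function(x, ...) {
  cat(sprintf("Harris-Boyd %s vs %s: z = %.3f, z* = %.3f, sd ratio = %.2f -> %s\n",
              x$group1$label, x$group2$label, x$z, x$z_star, x$sd_ratio,
              if (x$partition_required) "partition" else "combine"))
  invisible(x)
}

#' Pairwise partition scan over age/sex strata
#'
#' Runs [harris_boyd()] for (a) male vs female within each age band and
#' (b) age-band pairs within each sex — adjacent bands by default, all pairs
#' optionally. Summaries must come from transformed, outlier-screened
#' values. Missing strata are skipped with a warning. The overall
#' recommendation partitions on any dimension where any pairwise test
#' requires it.
#'
#' @param summaries A data frame with columns `sex`, `band`, `n`, `mean`,
#'   `sd` (one row per stratum).
#' @param analyte Analyte code, carried into the output.
#' @param mode `"adjacent"` or `"all-pairs"` for the within-sex band
#'   comparisons.
#' @param sd_ratio_limit Passed to [harris_boyd()].
#' @return A tibble with one row per comparison: `analyte`, `dimension`
#'   (`"sex"` or `"age"`), `comparison`, `n1`, `n2`, `z`, `z_star`,
#'   `sd_ratio`, `partition_required`; the per-dimension recommendation is
#'   in `attr(, "recommendation")`.
#' @export
partition_scan <- function(summaries, analyte = NA_character_,
                           mode = c("adjacent", "all-pairs"),
                           sd_ratio_limit = 1.5) {
  mode <- match.arg(mode)
  bands <- age_bands()$band
  gs <- function(sex, band) {
    row <- summaries[summaries$sex == sex & summaries$band == band, ]
    if (nrow(row) != 1) return(NULL)
    list(label = paste(sex, band), n = row$n, mean = row$mean, sd = row$sd)
  }
  full <- paste(rep(c("M", "F"), each = length(bands)), bands)
  present_lab <- paste(summaries$sex, summaries$band)
  absent <- setdiff(full, present_lab)
  if (length(absent) && length(present_lab)) {
    warning("missing stratum: ", paste(absent, collapse = ", "),
            "; comparisons involving it are skipped", call. = FALSE)
  }
  rows <- list()
  add <- function(dimension, g1, g2) {
    if (is.null(g1) || is.null(g2)) return(invisible())
    t <- harris_boyd(g1, g2, sd_ratio_limit = sd_ratio_limit)
    rows[[length(rows) + 1]] <<- tibble::tibble(
      analyte = analyte, dimension = dimension,
      comparison = paste(g1$label, "vs", g2$label),
      n1 = g1$n, n2 = g2$n, z = t$z, z_star = t$z_star,
      sd_ratio = t$sd_ratio, partition_required = t$partition_required)
  }
  present <- unique(summaries[c("sex", "band")])
  for (b in bands) {
    if (all(c("M", "F") %in% present$sex[present$band == b])) {
      add("sex", gs("M", b), gs("F", b))
    }
  }
  for (s in c("M", "F")) {
    have <- bands[bands %in% present$band[present$sex == s]]
    if (length(have) < 2) next
    pairs <- if (mode == "adjacent") {
      Map(c, have[-length(have)], have[-1])
    } else {
      utils::combn(have, 2, simplify = FALSE)
    }
    for (p in pairs) add("age", gs(s, p[1]), gs(s, p[2]))
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(analyte = character(), dimension = character(),
                   comparison = character(), n1 = integer(), n2 = integer(),
                   z = numeric(), z_star = numeric(), sd_ratio = numeric(),
                   partition_required = logical())
  attr(out, "recommendation") <- c(
    sex = any(out$partition_required[out$dimension == "sex"]),
    age = any(out$partition_required[out$dimension == "age"]))
  out
}
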