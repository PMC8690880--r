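# Shared fixtures: small cohorts and single-stratum model sets built in code.

# A spec with every stratum at the same small n; noise sources default to
# zero but can be overridden through `...`.
clean_spec <- function(n = 200, seed = 1, ...) {
  args <- list(seed = seed, n_per_stratum = n, ...)
  if (is.null(args$duplicate_fraction)) args$duplicate_fraction <- 0
  if (is.null(args$contamination_fraction)) args$contamination_fraction <- 0
  do.call(default_cohort_spec, args)
}

# Model set with no age trend and identical sexes (null for partitioning);
# lambda/mu/sigma taken from the default male models at age 22.
null_models <- function(sex_shift_sd = 0) {
  base <- default_stratum_models()
  out <- list()
  for (a in ri_analytes()$analyte) {
    m <- base[[paste0("M.", a)]]
    mu22 <- m$mu + 8 * m$slope
    out[[paste0("M.", a)]] <- stratum_model(a, "M", m$lambda, mu22, 0,
                                            m$sigma)
    out[[paste0("F.", a)]] <- stratum_model(a, "F", m$lambda,
                                            mu22 + sex_shift_sd * m$sigma,
                                            0, m$sigma)
  }
  out
}

# Spec concentrated in a single stratum (M 46-60 by default).
single_stratum_spec <- function(n, seed, stratum = "M 46-60", ...) {
  clean_spec(n = stats::setNames(n, stratum), seed = seed, ...)
}

# Hand-built tiny cohort data frame with valid values.
tiny_cohort_df <- function(n = 3) {
  data.frame(
    subject_id = sprintf("P%03d", seq_len(n)),
    name_key = sprintf("K%03d", seq_len(n)),
    sex = rep(c("M", "F"), length.out = n),
    age = seq(20, by = 7, length.out = n),
    visit_date = as.Date("2020-01-01") + seq_len(n),
    cd3_pct = 70 + seq_len(n), cd4_pct = 35 + seq_len(n),
    cd8_pct = 25 + seq_len(n),
    cd3_count = 1300 + 10 * seq_len(n), cd4_count = 630 + seq_len(n),
    cd8_count = 520 + seq_len(n))
}
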