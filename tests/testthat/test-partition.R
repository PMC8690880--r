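test_that("Harris-Boyd arithmetic matches the direct oracle", {
  g <- function(n, m, s, lab = "g") list(label = lab, n = n, mean = m, sd = s)
  t1 <- harris_boyd(g(120, 0, 1), g(120, 1, 1))
  expect_equal(t1$z, -sqrt(60), tolerance = 1e-12)   # |z| = 7.746
  expect_equal(abs(t1$z), 7.746, tolerance = 1e-3)
  expect_equal(t1$z_star, 3)
  expect_true(t1$partition_required)
  expect_true(t1$mean_criterion)
  expect_false(t1$sd_criterion)

  t2 <- harris_boyd(g(120, 0, 1), g(120, 0.2, 1))
  expect_equal(abs(t2$z), 1.549, tolerance = 1e-3)
  expect_false(t2$partition_required)

  # identical summaries
  t3 <- harris_boyd(g(500, 2, 1.2), g(500, 2, 1.2))
  expect_equal(t3$z, 0)
  expect_false(t3$partition_required)

  # symmetry: swapping groups negates z, keeps the decision
  t4 <- harris_boyd(g(200, 5, 2), g(300, 4, 1))
  t5 <- harris_boyd(g(300, 4, 1), g(200, 5, 2))
  expect_equal(t4$z, -t5$z)
  expect_equal(t4$partition_required, t5$partition_required)

  # SD-ratio secondary criterion
  t6 <- harris_boyd(g(400, 0, 2), g(400, 0, 1))
  expect_true(t6$sd_criterion)
  expect_true(t6$partition_required)
  t7 <- harris_boyd(g(400, 0, 2), g(400, 0, 1), sd_ratio_limit = Inf)
  expect_false(t7$partition_required)

  expect_error(harris_boyd(g(120, 0, 0), g(120, 1, 1)), "degenerate")
})

test_that("the decision is affine invariant and depends only on the
           standardized difference", {
  g <- function(n, m, s) list(label = "g", n = n, mean = m, sd = s)
  base <- harris_boyd(g(150, 10, 2), g(180, 11, 2.5))
  for (ab in list(c(3, -7), c(0.01, 100))) {
    tr <- harris_boyd(g(150, ab[1] * 10 + ab[2], abs(ab[1]) * 2),
                      g(180, ab[1] * 11 + ab[2], abs(ab[1]) * 2.5))
    expect_equal(abs(tr$z), abs(base$z), tolerance = 1e-12)
    expect_equal(tr$z_star, base$z_star)
    expect_equal(tr$sd_ratio, base$sd_ratio, tolerance = 1e-12)
  }
  # doubling both n scales |z| and z* by sqrt(2) alike
  d <- harris_boyd(g(300, 10, 2), g(360, 11, 2.5))
  expect_equal(abs(d$z) / abs(base$z), sqrt(2), tolerance = 1e-12)
  expect_equal(d$z_star / base$z_star, sqrt(2), tolerance = 1e-12)
})

test_that("partition scan flags a sex effect and stays quiet under the null", {
  make_summaries <- function(models, n, seed) {
    spec <- cohort_spec(models, n_per_stratum = n, seed = seed)
    co <- cohort_strata(generate_cohort(spec))
    a <- "cd3_count"
    lam <- models[["M.cd3_count"]]$lambda
    y <- boxcox_transform(co[[a]], lam)
    df <- tibble::tibble(sex = co$sex, band = co$band, y = y)
    dplyr::summarise(dplyr::group_by(df, sex, band),
                     n = dplyr::n(), mean = mean(y), sd = stats::sd(y),
                     .groups = "drop")
  }
  # null: identical sexes, no age trend
  s0 <- make_summaries(null_models(0), 5000, seed = 41)
  scan0 <- partition_scan(s0, analyte = "cd3_count")
  expect_equal(nrow(scan0), 13)  # 5 sex + 2 x 4 adjacent-age comparisons
  expect_false(any(scan0$partition_required))

  # one-sigma sex effect: every within-band sex comparison splits
  s1 <- make_summaries(null_models(1), 5000, seed = 42)
  scan1 <- partition_scan(s1, analyte = "cd3_count")
  sexrows <- scan1[scan1$dimension == "sex", ]
  expect_true(all(sexrows$partition_required))
  # z ~ sqrt(n/2) dwarfs z* = 3 sqrt(5000/120)
  expect_true(all(abs(sexrows$z) > 3 * sqrt(5000 / 120)))

  # all-pairs mode adds the non-adjacent comparisons
  scanall <- partition_scan(s1, analyte = "cd3_count", mode = "all-pairs")
  expect_equal(nrow(scanall), 5 + 2 * choose(5, 2))

  # scan result is independent of row order
  s1shuf <- s1[rev(seq_len(nrow(s1))), ]
  scan1b <- partition_scan(s1shuf, analyte = "cd3_count")
  expect_equal(scan1b, scan1)

  # a single stratum yields an empty table (plus a missing-strata warning)
  empty <- suppressWarnings(
    partition_scan(s1[s1$sex == "M" & s1$band == "14-30", ],
                   analyte = "cd3_count"))
  expect_equal(nrow(empty), 0)

  # a missing stratum is skipped with a warning
  expect_warning(partition_scan(s1[-1, ], analyte = "cd3_count"),
                 "missing stratum")
})
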