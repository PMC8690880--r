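test_that("verification applies the strict 5% rule", {
  ri <- list(lower = 10, upper = 20)
  v97 <- c(rep(15, 97), 5, 25, 30)
  r <- validate_ri(ri, v97)
  expect_equal(r$n_outside, 3)
  expect_equal(r$rate_outside, 0.03)
  expect_true(r$verified)

  v94 <- c(rep(15, 94), rep(5, 6))
  r2 <- validate_ri(ri, v94)
  expect_equal(r2$rate_outside, 0.06)
  expect_false(r2$verified)

  # exactly 5% fails (strict inequality)
  v95 <- c(rep(15, 95), rep(5, 5))
  expect_false(validate_ri(ri, v95)$verified)

  # boundary values are inside
  expect_equal(validate_ri(ri, c(rep(10, 50), rep(20, 50)))$n_outside, 0)

  expect_error(validate_ri(ri, rep(15, 5)), "at least 20")
})

test_that("widening an interval never increases the outside count", {
  set.seed(30)
  v <- rnorm(1000)
  r1 <- validate_ri(list(lower = -1, upper = 1), v)
  r2 <- validate_ri(list(lower = -1.5, upper = 1.2), v)
  r3 <- validate_ri(list(lower = -Inf, upper = Inf), v)
  expect_gte(r1$n_outside, r2$n_outside)
  expect_gte(r2$n_outside, r3$n_outside)
  expect_equal(r3$n_outside, 0)
})

test_that("a fresh draw from the generating model verifies its own RI", {
  spec <- single_stratum_spec(5000, seed = 61)
  co <- generate_cohort(spec)
  tab <- estimate_reference_intervals(co)
  fresh <- generate_cohort(single_stratum_spec(10000, seed = 62))
  rep <- verify_reference_intervals(tab, fresh)
  stratum_rows <- rep[rep$stratum != "all", ]
  # binomial sampling error at p = 0.05, n = 10,000 is ~0.2pp; allow the
  # estimation error of the n = 5,000 interval on top
  expect_true(all(abs(stratum_rows$rate_outside - 0.05) < 0.015))
  # the verified flag applies the strict rule to the observed rate
  expect_equal(stratum_rows$verified, stratum_rows$rate_outside < 0.05)
})

test_that("interval-set comparison detects a mismatched set", {
  # textbook 2x2 oracle: ((3, 97), (20, 80)) is significant at 1%
  counts <- matrix(c(3, 97, 20, 80), 2, byrow = TRUE)
  expect_lt(stats::chisq.test(counts, correct = FALSE)$p.value, 0.01)

  spec_old <- default_cohort_spec(
    n_per_stratum = c("M 76-100" = 2000), seed = 63,
    duplicate_fraction = 0, contamination_fraction = 0)
  old <- generate_cohort(spec_old)
  own <- estimate_reference_intervals(old)

  # an RI fit to young adults, applied unstratified to the elderly
  young <- generate_cohort(default_cohort_spec(
    n_per_stratum = c("M 14-30" = 2000), seed = 64,
    duplicate_fraction = 0, contamination_fraction = 0))
  ri_young <- estimate_reference_intervals(young)
  ri_young_all <- ri_young[ri_young$stratum == "all", ]

  fresh <- generate_cohort(default_cohort_spec(
    n_per_stratum = c("M 76-100" = 2000), seed = 65,
    duplicate_fraction = 0, contamination_fraction = 0))
  cmp <- compare_ri_sets(own, ri_young_all, fresh,
                         labels = c("own-stratum", "young-adult"))
  out_own <- cmp$counts["own-stratum", "outside"]
  out_young <- cmp$counts["young-adult", "outside"]
  expect_gt(out_young, out_own)
  expect_lt(cmp$p_value, 0.01)

  # identical sets give identical counts and p = 1
  same <- compare_ri_sets(own, own, fresh)
  expect_equal(same$counts[1, ], same$counts[2, ])
  expect_equal(same$p_value, 1, tolerance = 1e-9)

  # symmetry
  cmp2 <- compare_ri_sets(ri_young_all, own, fresh)
  expect_equal(cmp2$p_value, cmp$p_value, tolerance = 1e-12)
})

test_that("group-difference tests: null, power and degenerate input", {
  spec0 <- cohort_spec(null_models(0), n_per_stratum = 400, seed = 66)
  co0 <- generate_cohort(spec0)
  t0 <- group_difference_tests(co0, "cd3_count")
  expect_equal(nrow(t0), 3)  # KW per sex + MW
  expect_true(all(t0$p_value > 0.001))

  spec1 <- cohort_spec(null_models(1), n_per_stratum = 1000, seed = 67)
  co1 <- generate_cohort(spec1)
  t1 <- group_difference_tests(co1, "cd3_count")
  mw <- t1[t1$test == "mann-whitney", ]
  expect_lt(mw$p_value, 0.01)

  co_const <- co0
  co_const$cd3_count <- 500
  expect_error(group_difference_tests(co_const, "cd3_count"), "degenerate")
})

test_that("age trends recover sign and perfect monotonicity", {
  df <- tiny_cohort_df(40)
  df$sex <- "M"
  df$age <- 20:59
  df$cd3_pct <- 90 - 0.5 * df$age
  co <- as_cohort(df)
  tr <- age_trend(co, "cd3_pct", "M")
  expect_equal(tr$correlation, -1)
  expect_equal(tr$slope, -0.5, tolerance = 1e-9)

  spec <- clean_spec(n = 1000, seed = 68)
  co2 <- generate_cohort(spec)
  tr2 <- age_trend(co2, "cd3_count", "M")
  expect_lt(tr2$correlation, 0)
  expect_lt(tr2$slope, 0)

  # slope-0 model: OLS slope within 2 SEs of zero
  co0 <- generate_cohort(cohort_spec(null_models(0), 1000, seed = 69))
  tr0 <- age_trend(co0, "cd4_count", "F")
  fit <- stats::lm(co0$cd4_count[co0$sex == "F"] ~
                     co0$age[co0$sex == "F"])
  se <- summary(fit)$coefficients[2, 2]
  expect_lt(abs(tr0$slope), 2 * se)

  df$cd3_pct <- 50
  expect_warning(trc <- age_trend(as_cohort(df), "cd3_pct", "M"),
                 "constant")
  expect_true(is.na(trc$correlation))
})

test_that("extreme decline uses points for percentages, relative % for counts", {
  expect_equal(extreme_decline(70.05, 60.10, "percentage"), 9.95)
  expect_equal(round(extreme_decline(1309, 910, "absolute_count"), 2),
               30.48)
  expect_equal(extreme_decline(5, 5, "percentage"), 0)
  expect_equal(extreme_decline(5, 5, "absolute_count"), 0)
  # counts: scale invariance; percentages: shift equivariance of inputs
  expect_equal(extreme_decline(1309 * 3, 910 * 3, "absolute_count"),
               extreme_decline(1309, 910, "absolute_count"))
  expect_equal(extreme_decline(70.05 + 5, 60.10 + 5, "percentage"),
               extreme_decline(70.05, 60.10, "percentage"))
  expect_error(extreme_decline(0, -1, "absolute_count"), "positive")
})
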