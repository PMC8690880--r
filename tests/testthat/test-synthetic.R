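test_that("generation is deterministic and leaves the global RNG alone", {
  spec <- clean_spec(n = 60, seed = 7)
  set.seed(999)
  before <- .Random.seed
  c1 <- generate_cohort(spec)
  expect_identical(.Random.seed, before)
  c2 <- generate_cohort(spec)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  # a different seed changes the draw
  c3 <- generate_cohort(clean_spec(n = 60, seed = 8))
  expect_false(identical(c1$cd3_count, c3$cd3_count))
})

test_that("lambda = 1 models are affine and lambda = 0 lognormal", {
  # lambda = 1: x = y + 1, so Normal(999, 5) on the transformed scale
  # becomes Normal(1000, 5) observed
  m1 <- stratum_model("cd3_count", "M", lambda = 1, mu = 999, slope = 0,
                      sigma = 5)
  models <- default_stratum_models()
  models[["M.cd3_count"]] <- m1
  models[["M.cd4_count"]] <- stratum_model("cd4_count", "M", 1, 499, 0, 3)
  models[["M.cd8_count"]] <- stratum_model("cd8_count", "M", 1, 399, 0, 3)
  spec <- cohort_spec(models, n_per_stratum = c("M 46-60" = 4000), seed = 3)
  co <- generate_cohort(spec)
  expect_equal(mean(co$cd3_count), 1000, tolerance = 0.001)
  expect_equal(stats::sd(co$cd3_count), 5, tolerance = 0.05)

  # lambda = 0, mu = 0, sigma = 1: median of exp(Normal(0,1)) is 1
  m0 <- stratum_model("cd8_pct", "M", lambda = 0, mu = 0, slope = 0,
                      sigma = 1)
  models0 <- default_stratum_models()
  models0[["M.cd8_pct"]] <- m0
  spec0 <- cohort_spec(models0, n_per_stratum = c("M 31-45" = 20000),
                       seed = 5)
  co0 <- generate_cohort(spec0)
  expect_gt(stats::median(co0$cd8_pct), 0.95)
  expect_lt(stats::median(co0$cd8_pct), 1.05)
})

test_that("generated values respect ranges and the subset-sum constraint", {
  co <- generate_cohort(default_cohort_spec(n_per_stratum = 400, seed = 21,
                                            contamination_fraction = 0.05,
                                            contamination_scale = 5,
                                            duplicate_fraction = 0.2))
  for (a in c("cd3_pct", "cd4_pct", "cd8_pct")) {
    expect_true(all(co[[a]] >= 0 & co[[a]] <= 100))
  }
  for (a in c("cd3_count", "cd4_count", "cd8_count")) {
    expect_true(all(co[[a]] >= 0))
  }
  expect_true(all(co$cd4_count + co$cd8_count <= co$cd3_count + 1e-9))
  expect_true(all(co$age >= 14 & co$age <= 100))
})

test_that("negative transformed-scale slope gives declining band medians", {
  spec <- clean_spec(n = 2000, seed = 9)
  co <- cohort_strata(generate_cohort(spec))
  bands <- age_bands()$band
  for (a in c("cd3_pct", "cd3_count", "cd8_count")) {
    med <- vapply(bands, function(b)
      stats::median(co[[a]][co$sex == "M" & co$band == b]), numeric(1))
    # population medians are strictly decreasing; allow sampling slack on
    # the adjacent comparisons but demand overall decline
    expect_lt(med[length(med)], med[1])
    expect_true(all(diff(med) < 0.05 * med[-length(med)]))
  }
})

test_that("true_reference_interval matches closed forms", {
  m_ln <- stratum_model("cd3_count", "M", lambda = 0, mu = 0, slope = 0,
                        sigma = 1)
  q <- true_reference_interval(m_ln, "14-30")
  expect_equal(unname(q["lower"]), exp(-qnorm(0.975)), tolerance = 1e-6)
  expect_equal(unname(q["upper"]), exp(qnorm(0.975)), tolerance = 1e-6)
  expect_equal(unname(q["median"]), 1, tolerance = 1e-6)
  expect_equal(round(unname(q["lower"]), 4), 0.1409)
  expect_equal(round(unname(q["upper"]), 4), 7.0991)

  m_aff <- stratum_model("cd3_count", "M", lambda = 1, mu = 10, slope = 0,
                         sigma = 1)
  q <- true_reference_interval(m_aff, "46-60")
  expect_equal(unname(q["lower"]), 11 - qnorm(0.975), tolerance = 1e-6)
  expect_equal(unname(q["upper"]), 11 + qnorm(0.975), tolerance = 1e-6)
})

test_that("true_reference_interval matches a Monte-Carlo oracle", {
  # sqrt-family model: x = (0.5 y + 1)^2 with y ~ Normal(3, 0.4);
  # oracle is a direct seeded simulation, independent of the package path
  m <- stratum_model("cd3_count", "M", lambda = 0.5, mu = 3, slope = 0,
                     sigma = 0.4)
  q <- true_reference_interval(m, "31-45")
  set.seed(123)
  x <- (0.5 * rnorm(1e6, 3, 0.4) + 1)^2
  mc <- quantile(x, c(0.025, 0.5, 0.975), type = 7, names = FALSE)
  expect_equal(unname(q["lower"]), mc[1], tolerance = 0.005)
  expect_equal(unname(q["median"]), mc[2], tolerance = 0.005)
  expect_equal(unname(q["upper"]), mc[3], tolerance = 0.005)

  # with an age trend the quantiles are an age mixture: simulate that too
  mt <- stratum_model("cd3_count", "M", lambda = 0.5, mu = 3,
                      slope = -0.02, sigma = 0.4)
  qt <- true_reference_interval(mt, "31-45")
  set.seed(124)
  ages <- sample(31:45, 1e6, replace = TRUE)
  xt <- (0.5 * rnorm(1e6, 3 - 0.02 * (ages - 14), 0.4) + 1)^2
  mct <- quantile(xt, c(0.025, 0.975), type = 7, names = FALSE)
  expect_equal(unname(qt["lower"]), mct[1], tolerance = 0.005)
  expect_equal(unname(qt["upper"]), mct[2], tolerance = 0.005)
})

test_that("empirical percentiles at n = 20,000 match the truth table", {
  spec <- single_stratum_spec(20000, seed = 31)
  co <- generate_cohort(spec)
  truth <- cohort_truth(spec)
  for (a in c("cd3_pct", "cd3_count", "cd8_count")) {
    tr <- truth[truth$analyte == a, ]
    emp <- quantile(co[[a]], c(0.025, 0.975), type = 7, names = FALSE)
    expect_equal(emp[1], tr$lower, tolerance = 0.01)
    expect_equal(emp[2], tr$upper, tolerance = 0.01)
  }
})

test_that("an infeasible model is rejected with a clear error", {
  # sigma so large that the truncated mass outside [0, 100] is substantial
  expect_error(
    stratum_model("cd3_pct", "M", lambda = 2.450906, mu = 14000,
                  slope = 0, sigma = 8000),
    "outside the valid range")
  # count models whose medians already violate cd4 + cd8 <= cd3
  models <- default_stratum_models()
  models[["M.cd4_count"]] <- stratum_model("cd4_count", "M", 0, 7.6, 0, 0.3)
  expect_error(
    generate_cohort(cohort_spec(models, c("M 14-30" = 50), seed = 1)),
    "violate cd4 \\+ cd8")
})

test_that("duplicate injection is bookkept exactly", {
  spec <- default_cohort_spec(n_per_stratum = 250, seed = 13,
                              duplicate_fraction = 0.3,
                              contamination_fraction = 0)
  co <- generate_cohort(spec)
  n_base <- attr(co, "n_base")
  expect_equal(nrow(co), n_base + round(0.3 * n_base))
  dd <- deduplicate(co)
  expect_equal(dd$removed, round(0.3 * n_base))
  expect_equal(nrow(dd$cohort), n_base)
})
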