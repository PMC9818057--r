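test_that("the same spec, mechanism and seed reproduce the cohort exactly", {
  spec <- cohort_spec_vip2(n_patients = 400, seed = 99)
  mech <- mechanism_null()
  a <- generate_cohort(spec, mech)
  b <- generate_cohort(spec, mech)
  expect_identical(a, b)
  c <- generate_cohort(cohort_spec_vip2(n_patients = 400, seed = 100), mech)
  expect_false(identical(a$age, c$age))
})

test_that("a coefficient-free mechanism hits its marginal decision rates", {
  coh <- generate_cohort(cohort_spec(n_patients = 1000, seed = 5),
                         mechanism_null(p_withhold = 0.29))
  sigma <- sqrt(0.29 * 0.71 / 1000)
  expect_lt(abs(mean(coh$withhold) - 0.29), 3 * sigma)
})

test_that("VIP presets reproduce the published marginals within one unit", {
  coh <- generate_cohort(cohort_spec_vip1(seed = 11), mechanism_null())
  expect_identical(nrow(coh), 3727L)
  expect_lte(abs(stats::median(coh$age) - 84), 1)
  expect_lte(abs(stats::median(coh$cfs) - 4), 1)
  expect_lte(abs(stats::median(coh$sofa) - 7), 1)
  expect_lt(abs(mean(coh$gender == "female") - 0.482), 0.03)
  expect_true(all(coh$age >= 80))

  coh2 <- generate_cohort(cohort_spec_vip2(seed = 12), mechanism_null())
  expect_lte(abs(stats::median(coh2$sofa) - 6), 1)
  expect_lte(abs(stats::median(coh2$katz, na.rm = TRUE) - 6), 1)
  expect_lte(abs(stats::median(coh2$comorbidities, na.rm = TRUE) - 4), 1)
  # IQR endpoints of the core characteristics within one raw unit
  expect_lte(abs(stats::quantile(coh$age, 0.25) - 81), 1)
  expect_lte(abs(stats::quantile(coh$age, 0.75) - 87), 1)
  expect_lte(abs(stats::quantile(coh$cfs, 0.25) - 3), 1)
  expect_lte(abs(stats::quantile(coh$cfs, 0.75) - 6), 1)
  expect_lte(abs(stats::quantile(coh$sofa, 0.25) - 4), 1)
  expect_lte(abs(stats::quantile(coh$sofa, 0.75) - 11), 1)
})

test_that("invalid specs and unknown coefficients are rejected", {
  expect_error(cohort_spec(100, cfs_dist = rep(0.2, 9)),
               "probability vector")
  expect_error(cohort_spec(0), "at least 1")
  expect_error(cohort_spec(100, female_fraction = 1.2), "\\[0, 1\\]")
  expect_error(decision_mechanism(coefficients = c(heart_rate = 0.1)),
               "unknown coefficient")
  expect_error(
    generate_cohort(cohort_spec(50, seed = 1),
                    decision_mechanism(coefficients = list(
                      withdraw = c(katz = 0.2)))),
    "does not generate")
})

test_that("a one-bin category table makes the characteristic decisive", {
  mech <- decision_mechanism(
    mode = "category_table",
    category_table = list(withdraw = list(variable = "sofa",
                                          probs = c(rep(0, 7), 0.6))))
  coh <- generate_cohort(cohort_spec(n_patients = 3000, seed = 8), mech)
  expect_gt(sum(coh$withdraw), 0)
  expect_true(all(coh$sofa[coh$withdraw] > 13))
  # withholding falls back to its intercept rate
  expect_gt(mean(coh$withhold), 0.2)
})

test_that("demo likelihoods span uniform to point mass with concentration", {
  expect_equal(entropy(demo_likelihoods(8, 0, seed = 4)), 3)
  expect_lt(entropy(demo_likelihoods(8, 60, seed = 4)), 0.2)
  h_mid <- entropy(demo_likelihoods(8, 1.2, seed = 4))
  expect_gt(h_mid, 0)
  expect_lt(h_mid, 3)
  expect_error(demo_likelihoods(1, 0), "at least 2")
  # entropy decreases in expectation as concentration grows
  mean_h <- vapply(c(0.5, 1.5, 3), function(conc) {
    mean(vapply(1:30, function(s) entropy(demo_likelihoods(8, conc, s)),
                numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_h) < 0))
})
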