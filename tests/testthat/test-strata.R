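test_that("the zero-day stratum equals the unstratified frail analysis", {
  coh <- null_cohort(3000, seed = 81)
  st <- los_stratified_information(coh, frailty_threshold = 4,
                                   mlos_grid = c(0, 4),
                                   variables = c("age", "sofa"),
                                   decision = "withhold")
  frail <- coh[coh$cfs >= 4, ]
  direct <- information_summary(frail, "age", "withhold")
  row <- st[st$mlos == 0 & st$variable == "age", ]
  expect_equal(row$entropy_bits, direct$entropy_bits)
  expect_equal(row$n, direct$n_used)
  # strata shrink monotonically with the stay threshold
  for (v in unique(st$variable)) {
    expect_true(all(diff(st$n[st$variable == v]) <= 0))
  }
})

test_that("strata without decisions are flagged missing, not zero", {
  coh <- toy_cohort()
  st <- los_stratified_information(coh, frailty_threshold = 4,
                                   mlos_grid = c(0, 50),
                                   variables = "age", decision = "withdraw")
  expect_true(is.na(st$entropy_bits[st$mlos == 50]))
  expect_false(any(st$entropy_bits == 0, na.rm = TRUE))
  expect_error(los_stratified_information(coh, mlos_grid = c(4, 2)),
               "strictly increasing")
})

test_that("a stay-gated age effect surfaces only in long-stay strata", {
  mech <- decision_mechanism(
    los_model = list(family = "nbinom", size = 2, mu = 7),
    los_gate = list(decision = "withdraw", variable = "age",
                    coefficient = 0.35, min_los = 7))
  coh <- suppressMessages(apply_filters(
    generate_cohort(cohort_spec(n_patients = 8000, seed = 91), mech)))
  st <- los_stratified_information(coh, frailty_threshold = 4,
                                   mlos_grid = c(0, 8),
                                   variables = "age", decision = "withdraw")
  expect_lt(st$entropy_bits[st$mlos == 8], st$entropy_bits[st$mlos == 0])
})

test_that("small groups are excluded and the boundary is sharp", {
  coh <- null_cohort(1400, seed = 101)
  coh$country <- c(rep("BIG", 600), rep("EDGE", 499),
                   rep("SMALL", nrow(coh) - 1099))
  gi <- suppressMessages(grouped_information(coh, min_group_size = 500,
                                             variables = "sofa",
                                             decision = "withhold",
                                             n_reps = 20, seed = 3))
  expect_setequal(unique(gi$group), "BIG")
  expect_setequal(attr(gi, "excluded_groups"), c("EDGE", "SMALL"))
  expect_error(grouped_information(coh, min_group_size = 5000),
               "no group")
})

test_that("a single group reproduces the ungrouped analysis", {
  coh <- null_cohort(800, seed = 103)
  coh$country <- "ONLY"
  gi <- grouped_information(coh, min_group_size = 500, variables = "cfs",
                            decision = "withhold", n_reps = 20, seed = 5)
  direct <- information_summary(coh, "cfs", "withhold")
  expect_equal(gi$entropy_bits, direct$entropy_bits)
  expect_equal(gi$predictability, direct$predictability)
})

test_that("countries with different frailty weighting are distinguished", {
  mech_signal <- decision_mechanism(coefficients = list(
    withdraw = c(cfs = 0.5)))
  a <- generate_cohort(cohort_spec(n_patients = 2500, seed = 111,
                                   country_weights = c(CA = 1)),
                       mech_signal)
  b <- generate_cohort(cohort_spec(n_patients = 2500, seed = 112,
                                   country_weights = c(CB = 1)),
                       mechanism_null())
  coh <- suppressMessages(apply_filters(rbind(a, b)))
  gi <- grouped_information(coh, min_group_size = 500, variables = "cfs",
                            decision = "withdraw", n_reps = 60, seed = 7)
  gap <- abs(diff(gi$entropy_bits))
  pooled <- sqrt(sum(gi$entropy_sd^2))
  expect_gt(gap, 2 * pooled)
})
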