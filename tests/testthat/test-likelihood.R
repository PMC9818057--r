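test_that("likelihood distribution normalises conditional decision rates", {
  # bin 1: 10 patients, 2 decisions; bin 2: 10 patients, 6 decisions
  binned <- rep(1:2, each = 10)
  flags <- c(rep(TRUE, 2), rep(FALSE, 8), rep(TRUE, 6), rep(FALSE, 4))
  ell <- likelihood_distribution(binned, flags, n_bins = 2, pseudo = 0)
  expect_equal(ell$probs, c(0.25, 0.75)) # L = (0.2, 0.6) normalised
})

test_that("decisions confined to one bin give a point mass, entropy zero", {
  binned <- rep(1:8, each = 5)
  flags <- binned == 3
  ell <- likelihood_distribution(binned, flags, n_bins = 8, pseudo = 0)
  expect_equal(ell$probs[3], 1)
  expect_equal(entropy(ell), 0)
})

test_that("likelihood distribution rejects degenerate input", {
  expect_error(likelihood_distribution(1:4, rep(FALSE, 4), 4), "positive")
  expect_error(likelihood_distribution(c(1, 1, 3), c(TRUE, FALSE, TRUE),
                                       n_bins = 3, pseudo = 0),
               "zero patients")
  expect_error(likelihood_distribution(1:3, c(TRUE, FALSE), 3), "aligned")
  # missing bins are dropped with their flags
  ell <- likelihood_distribution(c(1, 2, NA, 1, 2), c(TRUE, TRUE, TRUE,
                                                      FALSE, FALSE),
                                 n_bins = 2, pseudo = 0)
  expect_equal(ell$probs, c(0.5, 0.5))
})

test_that("information summary reports entropy, maximum and predictability", {
  coh <- null_cohort(2000, seed = 21)
  s <- information_summary(coh, "sofa", "withhold")
  expect_lte(s$entropy_bits, s$h_max_bits)
  expect_equal(s$h_max_bits, 3)
  expect_equal(s$predictability,
               invert_predictability(s$entropy_bits, s$n_states))
  g <- information_summary(coh, "gender", "withhold")
  expect_equal(g$h_max_bits, 1)
})

test_that("pre/post divergence matches the two-term hand computation", {
  # 20 patients split 10/10 over 2 bins, decisions 2 vs 6:
  # P = (0.25, 0.75), Q = (0.5, 0.5), D_KL = 0.25 lg 0.5 + 0.75 lg 1.5
  coh <- data.frame(sofa = rep(c(0, 2), each = 10),
                    withdraw = c(rep(TRUE, 2), rep(FALSE, 8),
                                 rep(TRUE, 6), rep(FALSE, 4)))
  d <- pre_post_divergence(coh, "sofa", "withdraw",
                           binning_scheme(sofa = list(type = "interval",
                                                      origin = 0, width = 2,
                                                      n_bins = 2L)),
                           pseudo = 0)
  expect_equal(d$d_kl_bits, 0.1887219, tolerance = 1e-6)
  expect_equal(d$auroc, brute_auroc(c(2, 6), c(8, 4)))
})

test_that("null data satisfy the consistency triangle", {
  coh <- null_cohort(4000, seed = 31)
  s <- variable_summary(coh, "cfs", "withhold", n_reps = 60, seed = 31)
  expect_lt(abs(s$entropy_bits - s$h_max_bits), 3 * s$entropy_sd + 1e-3)
  expect_lt(s$d_kl_bits, 3 * s$d_kl_sd + 0.01)
  expect_lt(abs(s$auroc - 0.5), 0.05)
  # bootstrap mean close to the point estimate
  expect_lt(abs(s$entropy_mean - s$entropy_bits), 2 * s$entropy_sd + 1e-3)
})

test_that("a decisive characteristic separates nearly perfectly", {
  mech <- decision_mechanism(
    mode = "category_table",
    category_table = list(withdraw = list(variable = "sofa",
                                          probs = c(rep(0, 7), 0.6))))
  coh <- suppressMessages(apply_filters(
    generate_cohort(cohort_spec(n_patients = 4000, seed = 13), mech)))
  d <- pre_post_divergence(coh, "sofa", "withdraw")
  expect_gte(d$auroc, 0.95)
  s <- information_summary(coh, "sofa", "withdraw", pseudo = 0)
  expect_equal(s$entropy_bits, 0)
})
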