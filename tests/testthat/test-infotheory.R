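test_that("entropy matches hand-computed values and closed forms", {
  expect_equal(entropy(rep(1 / 8, 8)), 3)
  expect_equal(entropy(c(1, 0, 0, 0, 0, 0, 0, 0)), 0)
  expect_equal(entropy(c(0.5, 0.5)), 1)
  # four-term sum computed by hand: -(0.4 lg 0.4 + 0.3 lg 0.3 + 0.2 lg 0.2
  # + 0.1 lg 0.1)
  expect_equal(entropy(c(0.4, 0.3, 0.2, 0.1)), 1.8464393, tolerance = 1e-6)
  # permutation invariance
  expect_equal(entropy(c(0.1, 0.4, 0.2, 0.3)), entropy(c(0.4, 0.3, 0.2, 0.1)))
})

test_that("categorical distributions are validated", {
  expect_error(categorical_distribution(c(0.5, 0.6)), "sum to 1")
  expect_error(categorical_distribution(c(1)), "at least 2")
  expect_error(categorical_distribution(c(1.2, -0.2)), "\\[0, 1\\]")
  d <- categorical_distribution(c(0.25, 0.75), labels = c("a", "b"))
  expect_s3_class(d, "categorical_distribution")
  expect_identical(d$n, 2L)
})

test_that("maximum entropy is log2 of the bin count", {
  expect_equal(h_max(8), 3)
  expect_equal(round(h_max(7), 1), 2.8)
  expect_equal(h_max(4), 2)
  expect_equal(h_max(2), 1)
  expect_error(h_max(1), "at least 2")
})

test_that("predictability bound has the Fano form and uniform fixed point", {
  expect_equal(predictability_bound(1 / 8, 8), 3)
  # closed form at a hand value: pi = 0.5, n = 8 ->
  # -0.5 lg 0.5 - 0.5 lg 0.5 + 0.5 lg 7 = 1 + lg(7)/2
  expect_equal(predictability_bound(0.5, 8), 1 + log2(7) / 2)
  expect_error(predictability_bound(0, 8), "strictly in")
  expect_error(predictability_bound(1, 8), "strictly in")
})

test_that("inverting the bound reproduces the published conversions", {
  expect_equal(round(invert_predictability(2.78, 8), 2), 0.34)
  expect_equal(round(invert_predictability(2.80, 8), 2), 0.33)
  expect_equal(round(invert_predictability(2.91, 8), 2), 0.26)
  expect_equal(round(invert_predictability(2.95, 8), 2), 0.22)
  expect_equal(invert_predictability(3, 8), 0.125)
  expect_equal(invert_predictability(0, 8), 1)
  expect_error(invert_predictability(3.5, 8), "must lie in")
})

test_that("inversion is the identity on the upper branch and monotone", {
  for (n in c(2, 4, 7, 8)) {
    pis <- seq(1 / n + 1e-3, 0.999, length.out = 25)
    back <- invert_predictability(predictability_bound(pis, n), n)
    expect_equal(back, pis, tolerance = 1e-6)
  }
  h <- seq(0.1, 2.9, length.out = 20)
  expect_true(all(diff(invert_predictability(h, 8)) < 0))
})

test_that("KL divergence matches hand-computed values", {
  expect_equal(kl_divergence(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(kl_divergence(c(1, 0), c(0.5, 0.5)), 1)
  # two-term sum by hand: 0.7 lg(1.4) + 0.3 lg(0.6)
  expect_equal(kl_divergence(c(0.7, 0.3), c(0.5, 0.5)), 0.1187091,
               tolerance = 1e-6)
  expect_error(kl_divergence(c(0.5, 0.5), c(1, 0)), "zero cell")
  expect_error(kl_divergence(c(0.5, 0.5), c(0.2, 0.3, 0.5)), "same support")
  # smoothing keeps sparse cells finite and zero at identity
  expect_gt(kl_divergence(c(0.5, 0.5), c(1, 0), pseudo = 0.5), 0)
  expect_equal(kl_divergence(c(1, 0), c(1, 0), pseudo = 0.5), 0)
})

test_that("KL divergence is nonnegative on random pairs", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(2:10, 1)
    expect_gte(kl_divergence(random_dirichlet(n), random_dirichlet(n),
                             pseudo = 0.01), 0)
  }
})

test_that("entropy and KL are continuous under tiny perturbations", {
  p <- c(0.4, 0.3, 0.2, 0.1)
  q <- c(0.25, 0.25, 0.25, 0.25)
  eps <- c(1e-9, -1e-9, 0, 0)
  expect_lt(abs(entropy(p + eps) - entropy(p)), 1e-6)
  expect_lt(abs(kl_divergence(p + eps, q) - kl_divergence(p, q)), 1e-6)
})

test_that("binned-counts AUROC matches the all-pairs oracle", {
  expect_equal(auroc_from_binned_counts(c(3, 2, 5), c(3, 2, 5)), 0.5)
  expect_equal(auroc_from_binned_counts(c(0, 0, 0, 10), c(7, 0, 0, 0)), 1)
  expect_equal(auroc_from_binned_counts(c(1, 3), c(3, 1)),
               brute_auroc(c(1, 3), c(3, 1)))
  expect_equal(auroc_from_binned_counts(c(1, 3), c(3, 1)), 0.75)
  set.seed(7)
  for (i in 1:100) {
    nb <- sample(2:6, 1)
    pos <- stats::rmultinom(1, sample(1:20, 1), random_dirichlet(nb))[, 1]
    neg <- stats::rmultinom(1, sample(1:20, 1), random_dirichlet(nb))[, 1]
    expect_equal(auroc_from_binned_counts(pos, neg), brute_auroc(pos, neg))
  }
  expect_error(auroc_from_binned_counts(c(0, 0), c(1, 2)), "at least one")
})

test_that("binned-counts AUROC agrees with the rank-sum statistic", {
  pos <- c(2, 5, 1, 4)
  neg <- c(6, 2, 3, 1)
  w <- suppressWarnings(stats::wilcox.test(
    rep(1:4, pos), rep(1:4, neg)))$statistic
  expect_equal(auroc_from_binned_counts(pos, neg),
               unname(w) / (sum(pos) * sum(neg)))
})
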