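# shared fixtures and independent oracles, built in code

# 10-row toy cohort: rows 3 and 7 elective, row 5 missing SOFA
toy_cohort <- function() {
  data.frame(
    study_id = "TOY",
    age = c(81, 84, 90, 82, 88, 95, 97, 83, 86, 91),
    gender = rep(c("female", "male"), 5),
    cfs = c(3, 4, 5, 6, 2, 7, 8, 4, 5, 9),
    sofa = c(5, 7, 2, 10, NA, 13, 6, 4, 8, 11),
    admission_type = c("non_elective", "non_elective", "elective",
                       "non_elective", "non_elective", "non_elective",
                       "elective", "non_elective", "non_elective",
                       "non_elective"),
    withhold = c(TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE,
                 TRUE, FALSE),
    withdraw = c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE,
                 FALSE, FALSE),
    los_days = c(2, 5, 1, 9, 3, 12, 4, 6, 8, 2),
    country = rep(c("C01", "C02"), 5),
    stringsAsFactors = FALSE
  )
}

null_cohort <- function(n = 2000, seed = 1) {
  suppressMessages(apply_filters(
    generate_cohort(cohort_spec(n_patients = n, seed = seed),
                    mechanism_null())
  ))
}

# brute-force all-pairs AUROC oracle: expands counts to individual bin
# indices and averages the pairwise comparison with the half-tie rule
brute_auroc <- function(counts_pos, counts_neg) {
  pos <- rep(seq_along(counts_pos), counts_pos)
  neg <- rep(seq_along(counts_neg), counts_neg)
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

random_dirichlet <- function(n) {
  g <- stats::rgamma(n, shape = 1)
  g / sum(g)
}
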