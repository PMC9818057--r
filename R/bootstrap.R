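#' Bootstrap uncertainty of cohort-level information measures
#'
#' Resamples patients with replacement to the original cohort size,
#' recomputes a set of measures on each replicate, and reports their mean
#' and standard deviation across replicates — the accuracy estimate used
#' throughout the analysis (default 100 replicates).  A replicate on which
#' the measure fails (for example a resample without any decision-positive
#' patient) is skipped with a warning; if more than 10% of replicates skip,
#' the bootstrap aborts.
#'
#' @param cohort A cohort data frame.
#' @param measure_fn Function taking a resampled cohort and returning a
#'   named numeric vector of measures.
#' @param n_reps Number of bootstrap replicates, `>= 2`.
#' @param seed Integer seed; results are reproducible.
#' @return A data frame with one row per measure: `measure`, `mean`, `sd`,
#'   plus attributes `n_reps_used` and `n_skipped`.
#' @examples
#' coh <- generate_cohort(cohort_spec(n_patients = 300, seed = 2),
#'                        mechanism_null())
#' bootstrap_measures(coh, function(d) c(withhold_rate = mean(d$withhold)),
#'                    n_reps = 50, seed = 9)
#' @export
bootstrap_measures <- function(cohort, measure_fn, n_reps = 100, seed = 1L) {
  if (n_reps < 2) stop("n_reps must be at least 2")
  n <- nrow(cohort)
  if (n == 0L) stop("empty cohort")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  reps <- vector("list", n_reps)
  skipped <- 0L
  for (r in seq_len(n_reps)) {
    idx <- sample.int(n, n, replace = TRUE)
    res <- tryCatch(measure_fn(cohort[idx, , drop = FALSE]),
                    error = function(e) {
                      warning("bootstrap replicate ", r, " skipped: ",
                              conditionMessage(e), call. = FALSE)
                      NULL
                    })
    if (is.null(res)) skipped <- skipped + 1L else reps[r] <- list(res)
  }
  if (skipped > 0.1 * n_reps) {
    stop(skipped, " of ", n_reps, " bootstrap replicates failed (> 10%)")
  }
  mat <- do.call(rbind, reps[!vapply(reps, is.null, logical(1))])
  out <- data.frame(measure = colnames(mat),
                    mean = colMeans(mat),
                    sd = apply(mat, 2, stats::sd),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_reps_used") <- n_reps - skipped
  attr(out, "n_skipped") <- skipped
  out
}

#' Bootstrap-backed information and divergence summary for one variable
#'
#' Convenience wrapper combining the point estimates of
#' [information_summary()] and [pre_post_divergence()] with bootstrap
#' standard deviations of the entropy and the Kullback-Leibler divergence.
#'
#' @inheritParams information_summary
#' @param n_reps Bootstrap replicates.
#' @param seed Integer seed.
#' @return A one-row data frame with the point estimates plus
#'   `entropy_mean`, `entropy_sd`, `d_kl_mean`, `d_kl_sd`.
#' @export
variable_summary <- function(cohort, variable,
                             decision = c("withhold", "withdraw"),
                             scheme = binning_scheme(), pseudo = 0.5,
                             n_reps = 100, seed = 1L) {
  decision <- match.arg(decision)
  info <- information_summary(cohort, variable, decision, scheme, pseudo)
  div <- pre_post_divergence(cohort, variable, decision, scheme, pseudo)
  boot <- bootstrap_measures(cohort, function(d) {
    c(entropy = information_summary(d, variable, decision, scheme,
                                    pseudo)$entropy_bits,
      d_kl = pre_post_divergence(d, variable, decision, scheme,
                                 pseudo)$d_kl_bits)
  }, n_reps = n_reps, seed = seed)
  cbind(info,
        data.frame(d_kl_bits = div$d_kl_bits, auroc = div$auroc,
                   entropy_mean = boot$mean[boot$measure == "entropy"],
                   entropy_sd = boot$sd[boot$measure == "entropy"],
                   d_kl_mean = boot$mean[boot$measure == "d_kl"],
                   d_kl_sd = boot$sd[boot$measure == "d_kl"]))
}
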