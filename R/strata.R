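#' Entropy of decision likelihoods in frail patients by minimal length of stay
#'
#' Subanalysis of how the information used for treatment-limitation
#' decisions changes the longer vulnerable patients stay in ICU: restricts
#' the cohort to frail patients (CFS at or above `frailty_threshold`,
#' default 4) staying at least `mLOS` days, for each threshold in
#' `mlos_grid`, and recomputes the information summary per variable.  A
#' stratum without any decision-positive patient is reported with missing
#' entropy, not zero.
#'
#' @inheritParams information_summary
#' @param frailty_threshold Minimal CFS defining frailty (default 4).
#' @param mlos_grid Nonnegative, strictly increasing minimal-length-of-stay
#'   thresholds in days.
#' @param variables Characteristics to summarise.
#' @return A data frame with one row per `mlos` x `variable`: `mlos`,
#'   `variable`, `n`, `n_positive`, `entropy_bits`, `h_max_bits`,
#'   `predictability` (the last three `NA` for empty strata).
#' @export
los_stratified_information <- function(cohort, frailty_threshold = 4,
                                       mlos_grid = c(0, 2, 4, 6, 8, 10),
                                       variables = c("age", "cfs", "sofa"),
                                       decision = c("withhold", "withdraw"),
                                       scheme = binning_scheme(),
                                       pseudo = 0.5) {
  decision <- match.arg(decision)
  require_columns(cohort, c("cfs", "los_days", variables, decision))
  if (any(mlos_grid < 0) || is.unsorted(mlos_grid, strictly = TRUE)) {
    stop("mlos_grid must be nonnegative and strictly increasing")
  }
  rows <- list()
  for (mlos in mlos_grid) {
    sub <- cohort[!is.na(cohort$cfs) & cohort$cfs >= frailty_threshold &
                    !is.na(cohort$los_days) & cohort$los_days >= mlos, ,
                  drop = FALSE]
    for (v in variables) {
      res <- tryCatch(information_summary(sub, v, decision, scheme, pseudo),
                      error = function(e) NULL)
      rows[[length(rows) + 1L]] <- if (is.null(res)) {
        data.frame(mlos = mlos, variable = v, n = nrow(sub),
                   n_positive = sum(sub[[decision]], na.rm = TRUE),
                   entropy_bits = NA_real_, h_max_bits = NA_real_,
                   predictability = NA_real_, stringsAsFactors = FALSE)
      } else {
        data.frame(mlos = mlos, variable = v, n = res$n_used,
                   n_positive = res$n_positive,
                   entropy_bits = res$entropy_bits,
                   h_max_bits = res$h_max_bits,
                   predictability = res$predictability,
                   stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Per-group information summaries for large groups
#'
#' Computes bootstrap-backed information summaries separately for each level
#' of a grouping column (typically the contributing country), restricted to
#' groups with at least `min_group_size` patients (default 500, below which
#' entropy estimates are not considered robust).  Excluded groups are
#' reported in the `excluded_groups` attribute.
#'
#' @inheritParams variable_summary
#' @param group_key Name of the grouping column.
#' @param min_group_size Minimal group size for inclusion.
#' @param variables Characteristics to summarise.
#' @return A data frame with one row per group x variable: `group`, `n`,
#'   `variable`, `entropy_bits`, `entropy_sd`, `h_max_bits`,
#'   `predictability`; attribute `excluded_groups` names the groups below
#'   the threshold.
#' @export
grouped_information <- function(cohort, group_key = "country",
                                min_group_size = 500,
                                variables = c("age", "gender", "cfs", "sofa"),
                                decision = c("withhold", "withdraw"),
                                scheme = binning_scheme(), pseudo = 0.5,
                                n_reps = 100, seed = 1L) {
  decision <- match.arg(decision)
  require_columns(cohort, c(group_key, variables, decision))
  sizes <- table(cohort[[group_key]])
  keep_groups <- names(sizes)[sizes >= min_group_size]
  excluded <- setdiff(names(sizes), keep_groups)
  if (length(excluded)) {
    message("group(s) below the size threshold excluded: ",
            paste(excluded, collapse = ", "))
  }
  if (!length(keep_groups)) {
    stop("no group reaches the minimal size of ", min_group_size)
  }
  rows <- list()
  for (g in keep_groups) {
    sub <- cohort[cohort[[group_key]] == g, , drop = FALSE]
    for (v in variables) {
      info <- information_summary(sub, v, decision, scheme, pseudo)
      boot <- bootstrap_measures(sub, function(d) {
        c(entropy = information_summary(d, v, decision, scheme,
                                        pseudo)$entropy_bits)
      }, n_reps = n_reps, seed = seed)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, n = nrow(sub), variable = v,
        entropy_bits = info$entropy_bits, entropy_sd = boot$sd,
        h_max_bits = info$h_max_bits,
        predictability = info$predictability, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "excluded_groups") <- excluded
  out
}
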