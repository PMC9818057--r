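#' Published VIP study group sizes
#'
#' Cohort sizes of the two very-old-intensive-care-patients studies (VIP1,
#' VIP2) as published: all acutely admitted patients aged 80 or older, and
#' the subgroups with a documented decision to withhold or to withdraw
#' life-sustaining treatment.  Used to parameterise the synthetic presets
#' and as the arithmetic cross-check that the per-study decision counts add
#' up to the combined totals (7488 patients, 2186 withholding, 1110
#' withdrawing).
#'
#' @return A data frame with columns `study`, `n_all`, `n_withhold`,
#'   `n_withdraw` and one row per study.
#' @examples
#' colSums(vip_cohort_sizes()[, -1])
#' @export
vip_cohort_sizes <- function() {
  data.frame(study = c("VIP1", "VIP2"),
             n_all = c(3727L, 3761L),
             n_withhold = c(1070L, 1116L),
             n_withdraw = c(578L, 532L),
             stringsAsFactors = FALSE)
}
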