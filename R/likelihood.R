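counts_to_dist <- function(counts, pseudo = 0, labels = NULL) {
  sm <- counts + pseudo
  categorical_distribution(sm / sum(sm), labels = labels)
}

#' Normalised decision-likelihood distribution over a characteristic's bins
#'
#' The central construction of the analysis.  For each bin \eqn{x_i} of a
#' discretised characteristic, the decision likelihood is the conditional
#' rate \eqn{L(x_i) = P(\mathrm{decision} \mid X = x_i)}, estimated from
#' smoothed cell counts as `(d_i + pseudo) / (n_i + 2 * pseudo)` where `d_i`
#' of the `n_i` patients in bin i carry the decision.  The likelihoods are
#' then normalised into a probability distribution
#' \eqn{\ell(x_i) = L(x_i) / \sum_j L(x_j)}, whose Shannon entropy measures
#' how much information the characteristic carried for the decision: if the
#' decision is independent of the characteristic, \eqn{\ell} is uniform
#' (entropy `log2(N)`); if decisions occur in exactly one bin, \eqn{\ell} is
#' a point mass (entropy 0).
#'
#' @param binned_values Integer bin indices in `1..n_bins` (`NA` rows are
#'   dropped together with their flags).
#' @param decision_flags Logical decision indicators, aligned with
#'   `binned_values`; at least one must be `TRUE`.
#' @param n_bins Number of bins `N`.
#' @param pseudo Nonnegative pseudo-count added to each cell; the default
#'   0.5 keeps the likelihood defined in sparsely populated bins.  With
#'   `pseudo = 0`, an empty bin is an error.
#' @param labels Optional bin labels.
#' @return A [categorical_distribution] of length `n_bins`.
#' @examples
#' # two bins of 10 patients with 2 and 6 decisions: L = (0.2, 0.6),
#' # normalised to (0.25, 0.75)
#' likelihood_distribution(rep(1:2, each = 10),
#'                         rep(1:2, each = 10) == 2 & c(rep(TRUE, 16),
#'                                                      rep(FALSE, 4))[1:20],
#'                         n_bins = 2, pseudo = 0)
#' @export
likelihood_distribution <- function(binned_values, decision_flags, n_bins,
                                    pseudo = 0.5, labels = NULL) {
  if (length(binned_values) != length(decision_flags)) {
    stop("binned values and decision flags must be aligned")
  }
  keep <- !is.na(binned_values) & !is.na(decision_flags)
  b <- binned_values[keep]
  d <- decision_flags[keep]
  if (!any(d)) stop("no decision-positive rows")
  if (pseudo < 0) stop("pseudo must be nonnegative")
  n_i <- tabulate(b, nbins = n_bins)
  d_i <- tabulate(b[d], nbins = n_bins)
  if (pseudo == 0 && any(n_i == 0)) {
    stop("bin(s) with zero patients; use pseudo > 0 to smooth")
  }
  lik <- (d_i + pseudo) / (n_i + 2 * pseudo)
  categorical_distribution(lik / sum(lik), labels = labels)
}

#' Entropy, maximum entropy and predictability for one characteristic
#'
#' Bins the characteristic, forms the normalised decision-likelihood
#' distribution, and reports its Shannon entropy, the maximum entropy
#' `log2(N)`, and the Fano-type predictability upper bound obtained by
#' inverting the entropy (see [invert_predictability()]).  Rows with a
#' missing value of the characteristic are excluded listwise.
#'
#' @param cohort A filtered cohort data frame.
#' @param variable Characteristic name known to the binning scheme.
#' @param decision `"withhold"` or `"withdraw"`.
#' @param scheme A [binning_scheme].
#' @param pseudo Pseudo-count for the likelihood cells.
#' @return A one-row data frame of class `information_summary` with columns
#'   `variable`, `decision`, `n_used`, `n_positive`, `n_states`,
#'   `entropy_bits`, `h_max_bits`, `predictability`.
#' @export
information_summary <- function(cohort, variable,
                                decision = c("withhold", "withdraw"),
                                scheme = binning_scheme(), pseudo = 0.5) {
  decision <- match.arg(decision)
  require_columns(cohort, c(variable, decision))
  binned <- bin_variable(cohort[[variable]], variable, scheme)
  flags <- cohort[[decision]]
  keep <- !is.na(binned) & !is.na(flags)
  n_bins <- scheme_n_bins(scheme, variable)
  dist <- likelihood_distribution(binned, flags, n_bins, pseudo = pseudo,
                                  labels = bin_labels(scheme, variable))
  h <- entropy(dist)
  out <- data.frame(variable = variable, decision = decision,
                    n_used = sum(keep), n_positive = sum(flags[keep]),
                    n_states = n_bins, entropy_bits = h,
                    h_max_bits = h_max(n_bins),
                    predictability = invert_predictability(h, n_bins),
                    stringsAsFactors = FALSE)
  class(out) <- c("information_summary", "data.frame")
  out
}

#' Divergence of a characteristic's distribution before vs after a decision
#'
#' Compares the binned distribution of a characteristic among
#' decision-positive patients ("after", P) with its distribution among all
#' included patients ("before", Q) by the Kullback-Leibler divergence
#' \eqn{D_{KL}(P \| Q)} in bits, and additionally by the AUROC
#' discriminating decision-positive from decision-negative patients on the
#' binned scale.  A shift of the post-decision distribution indicates that
#' the decision revealed information about the characteristic; `D_KL = 0`
#' and AUROC 0.5 indicate none.
#'
#' @inheritParams information_summary
#' @return A one-row data frame of class `divergence_summary` with columns
#'   `variable`, `decision`, `n_used`, `n_positive`, `d_kl_bits`, `auroc`.
#' @export
pre_post_divergence <- function(cohort, variable,
                                decision = c("withhold", "withdraw"),
                                scheme = binning_scheme(), pseudo = 0.5) {
  decision <- match.arg(decision)
  require_columns(cohort, c(variable, decision))
  binned <- bin_variable(cohort[[variable]], variable, scheme)
  flags <- cohort[[decision]]
  keep <- !is.na(binned) & !is.na(flags)
  b <- binned[keep]
  d <- flags[keep]
  if (!any(d)) stop("no decision-positive rows")
  n_bins <- scheme_n_bins(scheme, variable)
  post <- tabulate(b[d], nbins = n_bins)
  pre <- tabulate(b, nbins = n_bins)
  neg <- pre - post
  dkl <- kl_divergence(counts_to_dist(post, pseudo),
                       counts_to_dist(pre, pseudo))
  out <- data.frame(variable = variable, decision = decision,
                    n_used = length(b), n_positive = sum(d),
                    d_kl_bits = dkl,
                    auroc = auroc_from_binned_counts(post, neg),
                    stringsAsFactors = FALSE)
  class(out) <- c("divergence_summary", "data.frame")
  out
}
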