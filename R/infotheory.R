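#' Categorical probability distribution over ordered bins
#'
#' Lightweight container for a probability vector over `N >= 2` mutually
#' distinct states (the bins of a discretised patient characteristic, or the
#' normalised decision-likelihood over those bins).
#'
#' @param probs Numeric vector of probabilities; each in `[0, 1]`, summing to
#'   1 within `1e-9`.
#' @param labels Optional character vector of bin labels (same length).
#' @return An object of class `categorical_distribution` with elements
#'   `probs`, `n` (number of states) and `labels`.
#' @examples
#' categorical_distribution(rep(1 / 8, 8))
#' @export
categorical_distribution <- function(probs, labels = NULL) {
  probs <- as.numeric(probs)
  if (length(probs) < 2L) {
    stop("a categorical distribution needs at least 2 states, got ",
         length(probs))
  }
  if (anyNA(probs) || any(probs < -1e-12) || any(probs > 1 + 1e-12)) {
    stop("probabilities must lie in [0, 1]")
  }
  if (abs(sum(probs) - 1) > 1e-9) {
    stop("probabilities must sum to 1 (got ", format(sum(probs)), ")")
  }
  if (!is.null(labels) && length(labels) != length(probs)) {
    stop("labels must match the number of states")
  }
  structure(
    list(probs = pmin(pmax(probs, 0), 1), n = length(probs), labels = labels),
    class = "categorical_distribution"
  )
}

#' @export
print.categorical_distribution <- function(x, ...) {
  cat("Categorical distribution over", x$n, "states\n")
  p <- round(x$probs, 4)
  names(p) <- x$labels %||% paste0("bin", seq_len(x$n))
  print(p)
  cat("entropy:", round(entropy(x), 4), "bits (max",
      round(h_max(x$n), 4), "bits)\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_prob_vector <- function(x, arg = "distribution") {
  if (inherits(x, "categorical_distribution")) return(x$probs)
  categorical_distribution(x)$probs
}

#' Shannon entropy of a categorical distribution
#'
#' Computes \eqn{H(X) = -\sum_i p(x_i) \log_2 p(x_i)} in bits, with the usual
#' convention \eqn{0 \log 0 = 0}.  Applied here to the normalised
#' decision-likelihood distribution over the bins of a patient
#' characteristic: low entropy means the characteristic carried much
#' information for the decision, entropy equal to \eqn{\log_2 N} means it was
#' uninformative.
#'
#' @param dist A [categorical_distribution] or a bare probability vector.
#' @return Entropy in bits, in `[0, log2(N)]`.
#' @examples
#' entropy(rep(1 / 8, 8)) # 3 bits
#' entropy(c(1, 0, 0, 0)) # 0 bits
#' @export
entropy <- function(dist) {
  p <- as_prob_vector(dist)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Maximum entropy of an N-state characteristic
#'
#' The entropy of the uniform distribution, \eqn{\log_2 N} bits: the value a
#' characteristic's decision-likelihood entropy takes when the characteristic
#' is uninformative.
#'
#' @param n Number of mutually distinct states (bins), `n >= 2`.
#' @return `log2(n)` in bits.
#' @examples
#' h_max(8) # 3
#' h_max(7) # 2.807...
#' @export
h_max <- function(n) {
  if (any(n < 2)) stop("n must be at least 2")
  log2(n)
}

#' Fano-type predictability bound
#'
#' Evaluates the entropy implied by an upper bound of predictability
#' \eqn{\Pi} for an N-state characteristic:
#' \deqn{H(\Pi) = -\Pi \log_2 \Pi - (1-\Pi)\log_2(1-\Pi) +
#'   (1-\Pi)\log_2(N-1).}
#' On the branch \eqn{\Pi \ge 1/N} this is a strictly decreasing function of
#' \eqn{\Pi} from \eqn{\log_2 N} (at \eqn{\Pi = 1/N}, the uniform fixed
#' point) towards 0, so an observed entropy can be inverted into the best
#' achievable fraction of correct category assignments; see
#' [invert_predictability()].
#'
#' @param pi Predictability, strictly inside `(0, 1)`; vectorised.
#' @param n Number of states, `n >= 2`.
#' @return Entropy in bits.
#' @examples
#' predictability_bound(1 / 8, 8) # 3 bits, the uniform fixed point
#' @export
predictability_bound <- function(pi, n) {
  if (any(n < 2)) stop("n must be at least 2")
  if (any(pi <= 0 | pi >= 1)) stop("pi must lie strictly in (0, 1)")
  -pi * log2(pi) - (1 - pi) * log2(1 - pi) + (1 - pi) * log2(n - 1)
}

#' Invert the predictability bound
#'
#' Solves `predictability_bound(pi, n) = h` for the root on the branch
#' \eqn{\Pi \in [1/N, 1]} by bisection to an absolute tolerance of `1e-9`.
#' This maps entropies of characteristics with different numbers of bins onto
#' one standardised scale: the largest fraction of patients that any decision
#' rule could correctly link to a category.  `h = log2(n)` gives the minimum
#' `1/n`; `h = 0` gives 1.
#'
#' @param h Entropy in bits, in `[0, log2(n)]`; vectorised.
#' @param n Number of states, `n >= 2`.
#' @return Predictability in `[1/n, 1]`.
#' @examples
#' round(invert_predictability(2.78, 8), 2) # 0.34
#' invert_predictability(3, 8) # 0.125
#' @export
invert_predictability <- function(h, n) {
  if (n < 2) stop("n must be at least 2")
  hmax <- log2(n)
  if (any(h < -1e-12 | h > hmax + 1e-12)) {
    stop("h must lie in [0, log2(n)] = [0, ", format(hmax), "]")
  }
  vapply(h, function(hi) {
    if (hi >= hmax - 1e-15) return(1 / n)
    if (hi <= 0) return(1)
    lo <- 1 / n          # f(lo) = hmax >= hi
    up <- 1 - 1e-15      # f(up) ~ 0 <= hi
    while (up - lo > 1e-9) {
      mid <- (lo + up) / 2
      if (predictability_bound(mid, n) > hi) lo <- mid else up <- mid
    }
    (lo + up) / 2
  }, numeric(1))
}

#' Kullback-Leibler divergence between two categorical distributions
#'
#' Computes \eqn{D_{KL}(P \| Q) = \sum_i p(x_i) \log_2 (p(x_i)/q(x_i))} in
#' bits, optionally after adding a pseudo-probability to every cell of both
#' vectors and renormalising (additive smoothing, keeping the divergence
#' finite when sparse bins are empty in `q`).  Zero if and only if the
#' (smoothed) distributions are identical.
#'
#' @param p,q [categorical_distribution] objects or probability vectors over
#'   the same support.
#' @param pseudo Nonnegative smoothing constant added to each cell before
#'   renormalising; default 0 (no smoothing).
#' @return Divergence in bits, `>= 0`.
#' @examples
#' kl_divergence(c(0.7, 0.3), c(0.5, 0.5)) # 0.1187 bits
#' @export
kl_divergence <- function(p, q, pseudo = 0) {
  p <- as_prob_vector(p)
  q <- as_prob_vector(q)
  if (length(p) != length(q)) stop("p and q must share the same support")
  if (pseudo < 0) stop("pseudo must be nonnegative")
  if (pseudo > 0) {
    p <- (p + pseudo) / (1 + length(p) * pseudo)
    q <- (q + pseudo) / (1 + length(q) * pseudo)
  }
  if (any(q == 0 & p > 0)) {
    stop("q has a zero cell where p is positive; use pseudo > 0 to smooth")
  }
  keep <- p > 0
  sum(p[keep] * log2(p[keep] / q[keep]))
}

#' AUROC between two binned count vectors
#'
#' The probability that a randomly drawn decision-positive patient has a
#' higher bin index than a randomly drawn decision-negative patient, counting
#' ties as one half (the Mann-Whitney statistic on the ordinal bin scale):
#' \eqn{P(X_{pos} > X_{neg}) + \tfrac12 P(X_{pos} = X_{neg})}.  0.5 indicates
#' no divergence between the two groups' distributions.
#'
#' @param counts_pos,counts_neg Nonnegative integer counts per bin, in bin
#'   order, same length; each must total at least 1.
#' @return AUROC in `[0, 1]`.
#' @examples
#' auroc_from_binned_counts(c(0, 10), c(10, 0)) # 1: perfect separation
#' @export
auroc_from_binned_counts <- function(counts_pos, counts_neg) {
  if (length(counts_pos) != length(counts_neg)) {
    stop("count vectors must have the same number of bins")
  }
  if (any(counts_pos < 0) || any(counts_neg < 0)) {
    stop("counts must be nonnegative")
  }
  n1 <- sum(counts_pos)
  n0 <- sum(counts_neg)
  if (n1 == 0 || n0 == 0) stop("both groups must contain at least one patient")
  neg_below <- cumsum(c(0, counts_neg[-length(counts_neg)]))
  u <- sum(counts_pos * (neg_below + 0.5 * counts_neg))
  u / (n1 * n0)
}
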