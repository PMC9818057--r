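---
title: "Measuring the information behind treatment-limitation decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the information behind treatment-limitation decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lstentropy)
```

## The problem

Decisions to withhold or withdraw life-sustaining treatment (LST) in very
old ICU patients involve substantial uncertainty.  `lstentropy` quantifies
how much information individual patient characteristics — severity of the
acute illness (SOFA score on admission), frailty (Clinical Frailty Scale,
CFS), age, gender, and the geriatric variables comorbidity count, Katz
index and pre-admission residence — contributed to these binary decisions
in cohorts of patients aged 80 years or older, such as the VIP1 and VIP2
multicentre studies.

The analysis does not ask whether decisions were *right*; it measures, in
bits, how strongly each characteristic was reflected in them.

## The model

Each characteristic is discretised into `N` ordered categories (see
"Binning" below).  For a decision type `d` (withhold or withdraw) and a
characteristic `X` with bins `x_1..x_N`, the **decision likelihood** per
bin is the conditional rate

$$L(x_i) = P(d \mid X = x_i),$$

estimated from cell counts with an additive pseudo-count.  Normalising the
likelihoods into a probability distribution,
$\ell(x_i) = L(x_i) / \sum_j L(x_j)$, yields the object whose Shannon
entropy

$$H(X) = -\sum_i \ell(x_i)\,\log_2 \ell(x_i)$$

measures the information the characteristic carried: if the decision is
independent of `X`, all conditional rates are equal, $\ell$ is uniform and
$H = \log_2 N$ (an uninformative characteristic); if decisions occur in a
single bin, $\ell$ is a point mass and $H = 0$ (a decisive one).  This
normalised-likelihood construction is the one definition consistent with
both limiting scenarios and with a per-variable maximum of `log2(N)`; it
is stated prominently here because reported entropies depend on it.

Entropies of variables with different `N` are made comparable through a
Fano-type bound.  The predictability upper limit $\Pi$ solves

$$H = -\Pi \log_2 \Pi - (1-\Pi)\log_2(1-\Pi) + (1-\Pi)\log_2(N-1),$$

on the branch $\Pi \in [1/N, 1]$, found by bisection to an absolute
tolerance of $10^{-9}$ (`invert_predictability()`).  The curve is not
injective on all of $(0,1)$; the upper branch is the one on which the
uniform distribution maps to $\Pi = 1/N$ and zero entropy to $\Pi = 1$,
and it reproduces the standard conversions for 8-bin variables
(`H = 2.78` bits gives $\Pi = 0.34$, `H = 3` gives `0.125`).  We write the
bound with the leading term negative; the form with a positive leading
term, which sometimes appears in print, cannot attain `log2(N)` at
$\Pi = 1/N$ and is a typographical slip.

Two complementary measures validate the entropy ranking
(`pre_post_divergence()`):

* the Kullback–Leibler divergence
  $D_{KL}(P\|Q) = \sum_i p_i \log_2(p_i/q_i)$ between the binned
  distribution of the characteristic among decision-positive patients
  (*after*, `P`) and among all included patients (*before*, `Q`); and
* the AUROC discriminating decision-positive from decision-negative
  patients on the binned scale, computed as the tie-corrected
  Mann–Whitney probability from the two count vectors.

`D_KL = 0` and AUROC `0.5` both indicate that the decision revealed
nothing about the characteristic.  We take the full included cohort, not
the decision-negative complement, as the *before* population: the
divergence then reads "information the decision reveals relative to the
admission case-mix", and the two decision types remain independently
analysable (a patient may carry both flags; no nesting of withdrawing
within withholding is imposed).

Uncertainty of `H` and `D_KL` is estimated by bootstrap: patients are
resampled with replacement to the original cohort size, the measure is
recomputed, and its standard deviation across replicates (default 100) is
reported.  The whole cohort is resampled, not strata: replicates without
any decision-positive patient are skipped with a warning, and more than
10% skipped replicates abort the analysis rather than silently biasing
the spread.

## Binning

Binning follows fixed clinical rules (`binning_scheme()`): age in 2-year
bins from 80 (80–81, …, 94–95) with older than 95 in bin 8; CFS one
category per bin with CFS 9 absorbed into bin 8; SOFA in 2-point bins
with scores above 15 in bin 8; comorbidity counts one per bin with counts
above 7 in bin 8; Katz 0–6 (7 bins); residence 4 categories; gender 2.
Two lower edges are not fixed by the published rules and are pinned here:
SOFA bins anchor at 0 (0–1, 2–3, …, 14–15), the only anchoring for which
eight 2-point bins exactly cover 0–15 with the stated overflow rule, and
comorbidity bin 1 is count 0, so that patients without comorbidities are
representable.  Bin indices are 1-based; values below a variable's domain
floor (e.g. age 79 in an 80+ cohort) are an error rather than silently
clamped, because they indicate corrupted input.  Missing values are
excluded listwise per characteristic-by-decision analysis and never
imputed.

## Inclusion filters

`apply_filters()` retains non-elective admissions with complete data on
the four core characteristics (age, gender, CFS, SOFA) and logs exclusion
counts.  `geriatric_subgroup()` additionally retains patients with less
than 20% missing data across the three geriatric variables; with three
variables, a single missing value already crosses that threshold, so
exactly the rows complete in all three remain.

## Tunable parameters

* `pseudo` (default 0.5, counts): additive smoothing applied to
  likelihood cells and to the pre/post count vectors before
  normalisation.  It keeps `L(x_i)` defined in sparsely populated bins
  and `D_KL` finite when a bin is empty after the decision, at the cost
  of a slight shrink toward uniformity that is negligible in dense bins.
  Whether the original analyses smoothed zero cells is not stated in
  print; reports based on sparse data should state the pseudo-count, and
  `pseudo = 0` restores the raw estimator (empty cells then error).
* `bootstrap_reps` (default 100) and `seed`: all resampling is seeded and
  reproducible.
* `frailty_threshold` (default CFS ≥ 4) and `mlos_grid`: the stay-
  stratified subanalysis (`los_stratified_information()`) recomputes the
  summaries among frail patients staying at least `mLOS` days; empty
  strata are reported as missing, never as zero entropy.
* `min_group_size` (default 500 patients): groups (countries) below this
  size are excluded from `grouped_information()` as too small for robust
  entropy estimates.

Logistic regression (`fit_decision_regression()`) cross-validates the
information ranking: one multivariable binomial GLM per decision, ordinal
characteristics entered as their bin index (so odds ratios read "per
1-bin increase"; entering them on raw scale is equally defensible, and
the binned scale is chosen so regression and information measures share
one discretisation), gender and residence as indicator contrasts with
male and home as references.  Wald 95% intervals are reported;
separation and non-convergence raise explicit warnings.

## The synthetic cohort generator

The VIP datasets are not publicly available, so `generate_cohort()`
produces cohorts with a *known* decision-generating mechanism against
which every pipeline stage is testable.  The presets `cohort_spec_vip1()`
and `cohort_spec_vip2()` emulate the published marginals: median age 84
(IQR 81–87, floored truncated normal with location 83 and scale 4.8),
CFS median 4 (IQR 3–6), SOFA medians 7 and 6 (negative-binomial
probability vectors), 48.2% / 46.7% female, and for the second study the
geriatric variables with a per-variable missing-completely-at-random rate
of 3.7%, which leaves about 89% of patients geriatric-complete — the
published subgroup fraction.  Decision flags follow an additive-logit
mechanism on the raw characteristics, centred at typical cohort values so
that `plogis(intercept)` is the marginal decision rate (defaults 29%
withholding, 15% withdrawing); a `category_table` mode instead assigns
decision probabilities directly per bin of one characteristic, which
constructs the illustrative uninformative / partially informative /
decisive scenarios exactly.  Length of stay is negative-binomial or
geometric, and an optional `los_gate` makes one coefficient act only
beyond a stay threshold, providing ground truth for the stay-stratified
analysis.

What the generator does **not** emulate: correlations between
characteristics (frail patients in real cohorts have more comorbidities),
informative missingness, within-centre clustering, and any survival
process.  Passing tests therefore demonstrate that the pipeline recovers
known mechanisms under clean conditions — not that real decision data
meet these assumptions.

## Numerical choices

All logarithms are base 2 (bits).  `0 log 0 = 0`.  Probability vectors
must sum to 1 within `1e-9`.  The bisection for $\Pi$ terminates at an
interval width of `1e-9`, and the inversion is exercised in tests as the
identity `invert(forward(pi)) = pi` to `1e-6` across the upper branch.
Degenerate inputs fail loudly: no decision-positive rows, empty groups,
empty strata and below-floor raw values are errors or flagged-missing
entries, never silent zeros.

## Problem sizes used in the tests

The packaged checks run at desk scale, chosen to keep the full suite
around a minute while leaving comfortable statistical margins: null and
mechanism-recovery cohorts of 5,000 patients with 100 bootstrap
replicates, calibration sweeps of 40 seeds at 600–3,700 patients, 1,000
random instances for the AUROC-versus-enumeration equivalence and 10,000
random pairs for nonnegativity of the divergence.

## Known limitations

Entropy is a global property of the likelihood distribution: it ignores
the ordering of bins and the location of peaks, so two very different
clinical patterns can share one entropy.  The predictability bound is an
upper limit, not an achievable rate.  Bootstrap SDs understate
uncertainty for near-uniform likelihoods where the plug-in entropy is
bias-limited rather than variance-limited.  Cross-characteristic
comparisons inherit the binning: a variable with fewer bins has a lower
entropy ceiling, which the predictability scale only partially absorbs.
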