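# lstentropy

Information-theoretic analysis of decisions to withhold or withdraw
life-sustaining treatment (LST) in very old ICU patients.

## The problem

In ICU cohorts of patients aged 80 years or older (such as the VIP1 and
VIP2 multicentre studies), treatment-limitation decisions are made under
substantial uncertainty. This package measures, in bits, how much
information each acute or geriatric patient characteristic — SOFA score on
admission, Clinical Frailty Scale (CFS), age, gender, comorbidity count,
Katz index, residence — contributed to those binary decisions, and ships a
synthetic cohort generator with known decision mechanisms so the whole
pipeline is testable without access to the (non-public) study data.

## The method

Each characteristic *X* is discretised into *N* ordered bins (age in
2-year bins from 80, SOFA in 2-point bins, one CFS category per bin, with
out-of-range-high values absorbed by the terminal bin). For a decision
type *d*, the per-bin decision likelihood *L(x_i) = P(d | X = x_i)* is
normalised into a probability distribution ℓ, and

- **Shannon entropy** H(X) = −Σ ℓ(x_i) log₂ ℓ(x_i) measures the
  information used: H = log₂N for an uninformative characteristic
  (uniform ℓ), H = 0 for a decisive one (point mass);
- the **predictability upper bound** Π solves the Fano-type equation
  H = −Π log₂Π − (1−Π) log₂(1−Π) + (1−Π) log₂(N−1) on the branch
  Π ∈ [1/N, 1], mapping entropies of variables with different N onto one
  scale (H = 2.78 bits with N = 8 gives Π = 0.34; H = 3 gives the minimum
  0.125);
- the **Kullback–Leibler divergence** D_KL(P‖Q) = Σ p log₂(p/q) between
  the characteristic's distribution after the decision (decision-positive
  patients) and before (all included patients), plus a binned-counts
  **AUROC**, validate the entropy ranking;
- **bootstrap** resampling (default 100 replicates) supplies standard
  deviations, and a multivariable **logistic regression** cross-checks the
  ranking with odds ratios.

## Worked example

Generate a VIP1-like cohort (3,727 patients, median age 84, CFS median 4,
SOFA median 7) in which, by construction, only the SOFA score influences
withdrawing decisions, then ask the pipeline which characteristic carried
information:

```r
library(lstentropy)

mech <- decision_mechanism(coefficients = list(withdraw = c(sofa = 0.15)))
coh  <- apply_filters(generate_cohort(cohort_spec_vip1(seed = 2026), mech))

for (v in c("age", "gender", "cfs", "sofa")) {
  s <- variable_summary(coh, v, "withdraw", n_reps = 100, seed = 1)
  cat(sprintf("%-6s H = %.2f ± %.3f (H_max %.1f)  Pi = %.2f  D_KL = %.3f  AUROC = %.2f\n",
              v, s$entropy_bits, s$entropy_sd, s$h_max_bits,
              s$predictability, s$d_kl_bits, s$auroc))
}
#> age    H = 2.98 ± 0.025 (H_max 3.0)  Pi = 0.18  D_KL = 0.007  AUROC = 0.50
#> gender H = 1.00 ± 0.002 (H_max 1.0)  Pi = 0.51  D_KL = 0.000  AUROC = 0.49
#> cfs    H = 2.99 ± 0.008 (H_max 3.0)  Pi = 0.17  D_KL = 0.009  AUROC = 0.49
#> sofa   H = 2.70 ± 0.029 (H_max 3.0)  Pi = 0.38  D_KL = 0.289  AUROC = 0.71
```

SOFA is correctly singled out: its likelihood entropy drops well below
the 3-bit maximum (up to 38% of patients could at best be linked to a
SOFA category from the decision alone), its post-decision distribution
diverges from the admission case-mix by 0.29 bits, and the AUROC moves
off 0.5. The unsignalled characteristics sit at their entropy ceilings.
The regression cross-check agrees — only SOFA's odds ratio leaves 1:

```r
fit_decision_regression(coh, c("age", "gender", "cfs", "sofa"), "withdraw")
#>           term   or ci_low ci_high
#> 1          age 0.98   0.93    1.04
#> 2 genderfemale 1.06   0.88    1.26
#> 3          cfs 0.98   0.94    1.03
#> 4         sofa 1.45   1.39    1.52
```

`run_pipeline(run_config(...))` executes the whole sequence — inclusion
filters, per-variable summaries with bootstrap SDs, regression,
frail-patient length-of-stay stratification, per-country comparison — and
writes JSON and CSV reports with a provenance record.

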