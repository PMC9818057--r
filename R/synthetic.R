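#' Specification of a synthetic very-old ICU cohort
#'
#' Describes the marginal distributions of a simulated cohort of ICU
#' patients aged 80 or older: a truncated, floored normal for age, a
#' probability vector over CFS 1..9, one over SOFA 0..24, optional
#' distributions for the geriatric variables (comorbidity count 0..10, Katz
#' index 0..6, residence in 4 categories), per-variable missingness rates,
#' the elective-admission fraction, and country mixture weights.  The
#' defaults emulate the published VIP-study marginals (median age 84, CFS
#' median 4 with IQR 3-6, SOFA median about 7, roughly 48% female); see
#' [cohort_spec_vip1()] and [cohort_spec_vip2()] for study-specific presets.
#'
#' @param n_patients Number of patients, `>= 1`.
#' @param study_label Label stored in the `study_id` column.
#' @param seed Integer seed; identical spec + mechanism + seed reproduce the
#'   cohort exactly.
#' @param age List with `location`, `scale`, `max`: ages are drawn as the
#'   floor of a normal(location, scale) truncated to `[80, max]`.
#' @param female_fraction Proportion of female patients in `[0, 1]`.
#' @param cfs_dist Probability vector over CFS 1..9 (length 9).
#' @param sofa_dist Probability vector over SOFA 0..24 (length 25).
#' @param comorbidity_dist Optional probability vector over counts 0..10.
#' @param katz_dist Optional probability vector over Katz 0..6 (length 7).
#' @param residence_dist Optional probability vector over the 4 residence
#'   categories (home, home with caregiver, nursing home/hospital, other).
#' @param missing_rates Named vector of per-variable missing-completely-at-
#'   random rates in `[0, 1]`.
#' @param elective_fraction Proportion of elective admissions.
#' @param country_weights Named probability vector of country mixture
#'   weights; names become country codes.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients,
                        study_label = "SYN",
                        seed = 1L,
                        age = list(location = 83, scale = 4.8, max = 105),
                        female_fraction = 0.48,
                        cfs_dist = c(0.04, 0.10, 0.18, 0.20, 0.16, 0.14,
                                     0.10, 0.05, 0.03),
                        sofa_dist = default_sofa_dist(8.2),
                        comorbidity_dist = NULL,
                        katz_dist = NULL,
                        residence_dist = NULL,
                        missing_rates = NULL,
                        elective_fraction = 0,
                        country_weights = c(C01 = 0.5, C02 = 0.5)) {
  spec <- structure(
    list(n_patients = as.integer(n_patients), study_label = study_label,
         seed = as.integer(seed), age = age,
         female_fraction = female_fraction, cfs_dist = cfs_dist,
         sofa_dist = sofa_dist, comorbidity_dist = comorbidity_dist,
         katz_dist = katz_dist, residence_dist = residence_dist,
         missing_rates = missing_rates,
         elective_fraction = elective_fraction,
         country_weights = country_weights),
    class = "cohort_spec"
  )
  validate_cohort_spec(spec)
  spec
}

default_sofa_dist <- function(mu, size = 3) {
  p <- stats::dnbinom(0:24, size = size, mu = mu)
  p / sum(p)
}

check_prob_vector <- function(p, name, len = NULL) {
  if (is.null(p)) return(invisible(NULL))
  if (!is.null(len) && length(p) != len) {
    stop(name, " must have length ", len, ", got ", length(p))
  }
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop(name, " must be a probability vector summing to 1")
  }
  invisible(NULL)
}

validate_cohort_spec <- function(spec) {
  if (spec$n_patients < 1L) stop("n_patients must be at least 1")
  fr <- c(female = spec$female_fraction, elective = spec$elective_fraction,
          spec$missing_rates)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  check_prob_vector(spec$cfs_dist, "cfs_dist", 9)
  check_prob_vector(spec$sofa_dist, "sofa_dist", 25)
  check_prob_vector(spec$comorbidity_dist, "comorbidity_dist", 11)
  check_prob_vector(spec$katz_dist, "katz_dist", 7)
  check_prob_vector(spec$residence_dist, "residence_dist", 4)
  check_prob_vector(spec$country_weights, "country_weights")
  bad <- setdiff(names(spec$missing_rates),
                 c(core_variables, geriatric_variables, "los_days"))
  if (length(bad)) stop("unknown variable(s) in missing_rates: ",
                        paste(bad, collapse = ", "))
  invisible(spec)
}

#' VIP1-like cohort specification
#'
#' Preset emulating the first very-old-intensive-care-patients study
#' marginals: 3727 acutely admitted patients, median age 84, CFS median 4
#' (IQR 3-6), SOFA median 7 (IQR 4-11), 48.2% female, no geriatric
#' variables recorded.
#'
#' @param n_patients Cohort size; defaults to the published study size.
#' @param seed Integer seed.
#' @return A [cohort_spec].
#' @export
cohort_spec_vip1 <- function(n_patients = 3727, seed = 1L) {
  cohort_spec(n_patients, study_label = "VIP1", seed = seed,
              female_fraction = 0.482, sofa_dist = default_sofa_dist(8.2))
}

#' VIP2-like cohort specification
#'
#' Preset emulating the second study's marginals: 3761 patients, 46.7%
#' female, SOFA median 6 (IQR 4-9), with the geriatric variables
#' (comorbidities median 4, Katz median 6, residence mostly home) recorded
#' and a small per-variable missingness rate such that roughly 89% of
#' patients have complete geriatric data.
#'
#' @inheritParams cohort_spec_vip1
#' @return A [cohort_spec].
#' @export
cohort_spec_vip2 <- function(n_patients = 3761, seed = 1L) {
  com <- stats::dpois(0:10, 4.3)
  cohort_spec(n_patients, study_label = "VIP2", seed = seed,
              female_fraction = 0.467, sofa_dist = default_sofa_dist(7),
              comorbidity_dist = com / sum(com),
              katz_dist = c(0.04, 0.04, 0.06, 0.08, 0.12, 0.14, 0.52),
              residence_dist = c(2510, 357, 451, 40) / 3358,
              missing_rates = c(comorbidities = 0.037, katz = 0.037,
                                residence = 0.037))
}

#' Decision-generating mechanism for synthetic cohorts
#'
#' Ground-truth link between patient characteristics and the two
#' treatment-limitation decisions.  In `logistic` mode each decision flag is
#' Bernoulli with log-odds
#' `intercept + sum_k coef_k * (x_k - center_k)`, on the raw (unbinned)
#' characteristic scale, with gender entered as a female indicator.  Because
#' coefficients are centred at typical cohort values, `plogis(intercept)`
#' is approximately the marginal decision rate.  In `category_table` mode a
#' decision's probability is looked up directly from the bin of one
#' characteristic, which constructs the illustrative scenarios exactly: a
#' constant table gives an uninformative characteristic (uniform
#' likelihood), a one-bin table a decisive one (point-mass likelihood).
#'
#' An optional `los_gate` restricts one coefficient to patients whose ICU
#' length of stay exceeds a threshold, providing ground truth for
#' stay-stratified analyses.
#'
#' @param intercept_withhold,intercept_withdraw Log-odds intercepts; the
#'   defaults give marginal rates of about 29% withholding and 15%
#'   withdrawing.
#' @param coefficients Either a single named numeric vector (applied to both
#'   decisions) or `list(withhold = ..., withdraw = ...)`; names must be
#'   characteristics present in the cohort (`age`, `gender`, `cfs`, `sofa`,
#'   `comorbidities`, `katz`).  Units are log-odds per raw unit (per year of
#'   age, per CFS point, ...).
#' @param centering Named numeric vector of centring constants; defaults to
#'   typical values (age 84, CFS 4.5, SOFA 8, comorbidities 4, Katz 5,
#'   gender 0.5).
#' @param los_model Length-of-stay model: `list(family = "nbinom", size,
#'   mu)` or `list(family = "geometric", prob)`, in days.
#' @param mode `"logistic"` or `"category_table"`.
#' @param category_table For `category_table` mode:
#'   `list(withhold = list(variable, probs), withdraw = ...)` with `probs`
#'   indexed by the variable's bin; a decision without an entry falls back
#'   to its intercept rate.
#' @param los_gate Optional `list(decision, variable, coefficient,
#'   min_los)`: the extra coefficient applies only when `los_days >
#'   min_los`.
#' @return An object of class `decision_mechanism`.
#' @export
decision_mechanism <- function(intercept_withhold = stats::qlogis(0.29),
                               intercept_withdraw = stats::qlogis(0.15),
                               coefficients = NULL,
                               centering = NULL,
                               los_model = list(family = "nbinom",
                                                size = 2, mu = 6),
                               mode = c("logistic", "category_table"),
                               category_table = NULL,
                               los_gate = NULL) {
  mode <- match.arg(mode)
  default_center <- c(age = 84, gender = 0.5, cfs = 4.5, sofa = 8,
                      comorbidities = 4, katz = 5)
  center <- default_center
  center[names(centering)] <- centering
  if (!is.null(coefficients) && !is.list(coefficients)) {
    coefficients <- list(withhold = coefficients, withdraw = coefficients)
  }
  mech <- structure(
    list(intercepts = c(withhold = intercept_withhold,
                        withdraw = intercept_withdraw),
         coefficients = coefficients, centering = center,
         los_model = los_model, mode = mode,
         category_table = category_table, los_gate = los_gate),
    class = "decision_mechanism"
  )
  allowed <- names(default_center)
  for (dec in names(mech$coefficients)) {
    bad <- setdiff(names(mech$coefficients[[dec]]), allowed)
    if (length(bad)) {
      stop("unknown coefficient name(s): ", paste(bad, collapse = ", "))
    }
  }
  mech
}

#' Coefficient-free decision mechanism
#'
#' Decisions drawn independently of every characteristic, at fixed marginal
#' rates: the null condition under which every likelihood distribution is
#' uniform in expectation and every AUROC is 0.5.
#'
#' @param p_withhold,p_withdraw Marginal decision probabilities.
#' @return A [decision_mechanism] with no coefficients.
#' @export
mechanism_null <- function(p_withhold = 0.29, p_withdraw = 0.15) {
  decision_mechanism(intercept_withhold = stats::qlogis(p_withhold),
                     intercept_withdraw = stats::qlogis(p_withdraw))
}

draw_los <- function(n, los_model) {
  switch(los_model$family,
         nbinom = stats::rnbinom(n, size = los_model$size, mu = los_model$mu),
         geometric = stats::rgeom(n, prob = los_model$prob),
         stop("unknown length-of-stay family '", los_model$family, "'"))
}

decision_probability <- function(decision, mech, raw, los_days,
                                 scheme = binning_scheme()) {
  n <- length(los_days)
  if (mech$mode == "category_table" &&
      !is.null(mech$category_table[[decision]])) {
    tab <- mech$category_table[[decision]]
    idx <- bin_variable(raw[[tab$variable]], tab$variable, scheme)
    if (length(tab$probs) != scheme_n_bins(scheme, tab$variable)) {
      stop("category_table probs for '", tab$variable,
           "' must have one entry per bin")
    }
    return(tab$probs[idx])
  }
  eta <- rep(mech$intercepts[[decision]], n)
  coefs <- mech$coefficients[[decision]]
  for (nm in names(coefs)) {
    x <- raw[[nm]]
    if (is.null(x)) {
      stop("coefficient refers to '", nm, "', which the cohort spec ",
           "does not generate")
    }
    eta <- eta + coefs[[nm]] * (x - mech$centering[[nm]])
  }
  gate <- mech$los_gate
  if (!is.null(gate) && identical(gate$decision, decision)) {
    x <- raw[[gate$variable]]
    eta <- eta + ifelse(los_days > gate$min_los,
                        gate$coefficient * (x - mech$centering[[gate$variable]]),
                        0)
  }
  stats::plogis(eta)
}

#' Generate a synthetic cohort
#'
#' Draws one row per patient from the marginals in `spec`, the length of
#' stay from the mechanism's stay model, and the two decision flags from the
#' mechanism (withholding and withdrawing are generated as two mechanisms
#' over shared covariates, with no nesting imposed: both flags may be true).
#' Missing values are then injected missing-completely-at-random per
#' `spec$missing_rates`.  The same spec, mechanism and seed reproduce the
#' table exactly; the seed and settings are attached as a `provenance`
#' attribute that [write_cohort()] can emit as a sidecar file.
#'
#' @param spec A [cohort_spec].
#' @param mechanism A [decision_mechanism].
#' @return A cohort data frame with columns `study_id`, `age`, `gender`,
#'   `cfs`, `sofa`, `admission_type`, `withhold`, `withdraw`, `los_days`,
#'   `country` and, when the spec provides distributions, `comorbidities`,
#'   `katz`, `residence`.
#' @examples
#' coh <- generate_cohort(cohort_spec(n_patients = 500, seed = 7),
#'                        mechanism_null())
#' mean(coh$withhold)
#' @export
generate_cohort <- function(spec, mechanism) {
  validate_cohort_spec(spec)
  stopifnot(inherits(mechanism, "decision_mechanism"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)

  n <- spec$n_patients
  f80 <- stats::pnorm(80, spec$age$location, spec$age$scale)
  fmax <- stats::pnorm(spec$age$max + 1, spec$age$location, spec$age$scale)
  age <- floor(stats::qnorm(f80 + stats::runif(n) * (fmax - f80),
                            spec$age$location, spec$age$scale))
  age <- pmin(age, spec$age$max)
  gender <- ifelse(stats::runif(n) < spec$female_fraction, "female", "male")
  cfs <- sample(1:9, n, replace = TRUE, prob = spec$cfs_dist)
  sofa <- sample(0:24, n, replace = TRUE, prob = spec$sofa_dist)
  comorbidities <- if (!is.null(spec$comorbidity_dist))
    sample(0:10, n, replace = TRUE, prob = spec$comorbidity_dist)
  katz <- if (!is.null(spec$katz_dist))
    sample(0:6, n, replace = TRUE, prob = spec$katz_dist)
  residence <- if (!is.null(spec$residence_dist))
    sample(c("home", "home_with_caregiver", "nursing_home_or_hospital",
             "other"), n, replace = TRUE, prob = spec$residence_dist)
  admission_type <- ifelse(stats::runif(n) < spec$elective_fraction,
                           "elective", "non_elective")
  country <- sample(names(spec$country_weights), n, replace = TRUE,
                    prob = spec$country_weights)
  los_days <- as.numeric(draw_los(n, mechanism$los_model))

  raw <- list(age = age, gender = as.integer(gender == "female"),
              cfs = cfs, sofa = sofa, comorbidities = comorbidities,
              katz = katz)
  raw_char <- list(age = age, gender = gender, cfs = cfs, sofa = sofa,
                   comorbidities = comorbidities, katz = katz,
                   residence = residence)
  withhold <- stats::runif(n) <
    decision_probability("withhold", mechanism, raw, los_days)
  withdraw <- stats::runif(n) <
    decision_probability("withdraw", mechanism, raw, los_days)

  cohort <- data.frame(study_id = spec$study_label, age = age,
                       gender = gender, cfs = cfs, sofa = sofa,
                       admission_type = admission_type,
                       withhold = withhold, withdraw = withdraw,
                       los_days = los_days, country = country,
                       stringsAsFactors = FALSE)
  for (nm in geriatric_variables) {
    if (!is.null(raw_char[[nm]])) cohort[[nm]] <- raw_char[[nm]]
  }
  for (nm in names(spec$missing_rates)) {
    if (!nm %in% names(cohort)) next
    miss <- stats::runif(n) < spec$missing_rates[[nm]]
    cohort[[nm]][miss] <- NA
  }
  attr(cohort, "provenance") <- list(
    generator = "lstentropy::generate_cohort",
    package_version = as.character(utils::packageVersion("lstentropy")),
    seed = spec$seed, n_patients = n, study_label = spec$study_label,
    mechanism_mode = mechanism$mode)
  cohort
}

#' Simulated decision-likelihood distribution
#'
#' Emits a hypothetical normalised likelihood distribution over `n_bins`
#' categories whose concentration is controlled by a single parameter:
#' weights are `exp(concentration * z)` with `z` standard normal per bin,
#' renormalised.  Concentration 0 gives exactly the uniform distribution
#' (maximum entropy, an uninformative characteristic); as concentration
#' grows the distribution approaches a point mass (entropy 0, a decisive
#' characteristic), with entropy decreasing in expectation in between.
#'
#' @param n_bins Number of categories, `>= 2`.
#' @param concentration Nonnegative concentration parameter.
#' @param seed Integer seed.
#' @return A [categorical_distribution].
#' @examples
#' entropy(demo_likelihoods(8, 0, 1))   # exactly 3 bits
#' entropy(demo_likelihoods(8, 50, 1))  # near 0
#' @export
demo_likelihoods <- function(n_bins, concentration, seed = 1L) {
  if (n_bins < 2) stop("n_bins must be at least 2")
  if (concentration < 0) stop("concentration must be nonnegative")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  w <- exp(concentration * stats::rnorm(n_bins))
  categorical_distribution(w / sum(w))
}
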