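Package: lstentropy
Title: Information-Theoretic Analysis of Life-Sustaining Treatment
    Decisions in Very Old ICU Patients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies how much information individual acute and geriatric
    patient characteristics (SOFA score, Clinical Frailty Scale, age, gender,
    comorbidities, Katz index, residence) contributed to decisions to withhold
    or withdraw life-sustaining treatment in intensive-care cohorts of
    patients aged 80 years or older.  Characteristics are binned into ordered
    categories, the per-category decision likelihood is normalised into a
    probability distribution, and its Shannon entropy, a Fano-type
    predictability upper bound, the Kullback-Leibler divergence between pre-
    and post-decision covariate distributions, and a binned-counts AUROC are
    reported with bootstrap uncertainty.  Includes a synthetic cohort
    generator with configurable logistic decision mechanisms emulating the
    VIP1/VIP2 very-old-intensive-care-patient studies, logistic-regression
    cross-validation of the information ranking, Kolmogorov-Smirnov cohort
    comparison, and length-of-stay and country-stratified subanalyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
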