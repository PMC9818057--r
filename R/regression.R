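#' Multivariable logistic regression of a decision on patient characteristics
#'
#' The cross-validation of the information ranking: fits a single logistic
#' model of the decision flag on all listed characteristics and reports an
#' odds ratio with Wald 95% confidence interval per term.  Ordinal
#' characteristics (age, CFS, SOFA, comorbidities, Katz) enter as their
#' binned index, so odds ratios read "per 1-bin increase"; gender and
#' residence enter as indicator contrasts with male and home as the
#' reference levels.  Rows with a missing value in any listed variable are
#' dropped; separation or non-convergence is reported explicitly as a
#' warning on the returned object.
#'
#' @inheritParams information_summary
#' @param variables Character vector of characteristics to include.
#' @return A data frame of class `decision_regression` with columns `term`,
#'   `estimate` (log odds), `or`, `ci_low`, `ci_high`, `p_value`, and
#'   attributes `n_used` and `converged`.
#' @export
fit_decision_regression <- function(cohort, variables,
                                    decision = c("withhold", "withdraw"),
                                    scheme = binning_scheme()) {
  decision <- match.arg(decision)
  require_columns(cohort, c(variables, decision))
  ordinal <- c("age", "cfs", "sofa", "comorbidities", "katz")
  mf <- data.frame(.y = cohort[[decision]])
  for (v in variables) {
    mf[[v]] <- if (v %in% ordinal) {
      as.numeric(bin_variable(cohort[[v]], v, scheme))
    } else if (v == "gender") {
      factor(cohort[[v]], levels = c("male", "female"))
    } else if (v == "residence") {
      factor(cohort[[v]], levels = c("home", "home_with_caregiver",
                                     "nursing_home_or_hospital", "other"))
    } else {
      cohort[[v]]
    }
  }
  mf <- mf[stats::complete.cases(mf), , drop = FALSE]
  if (nrow(mf) == 0L) stop("no complete rows for regression")
  fit <- stats::glm(.y ~ ., data = mf, family = stats::binomial())
  if (!fit$converged) {
    warning("logistic regression did not converge", call. = FALSE)
  }
  co <- summary(fit)$coefficients
  co <- co[rownames(co) != "(Intercept)", , drop = FALSE]
  if (any(abs(co[, "Estimate"]) > 10 | co[, "Std. Error"] > 100)) {
    warning("very large coefficient(s); possible separation", call. = FALSE)
  }
  out <- data.frame(term = rownames(co),
                    estimate = co[, "Estimate"],
                    or = exp(co[, "Estimate"]),
                    ci_low = exp(co[, "Estimate"] -
                                   1.96 * co[, "Std. Error"]),
                    ci_high = exp(co[, "Estimate"] +
                                    1.96 * co[, "Std. Error"]),
                    p_value = co[, "Pr(>|z|)"],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_used") <- nrow(mf)
  attr(out, "converged") <- fit$converged
  class(out) <- c("decision_regression", "data.frame")
  out
}

#' Compare the distribution of a characteristic between two cohorts
#'
#' Two-sample Kolmogorov-Smirnov test on the raw (unbinned) values, used to
#' check whether two study populations can be pooled or must be analysed
#' separately.
#'
#' @param cohort_a,cohort_b Cohort data frames.
#' @param variable Characteristic name present in both.
#' @return A one-row data frame with `variable`, `statistic` (the KS D) and
#'   `p_value`.
#' @export
compare_cohorts <- function(cohort_a, cohort_b, variable) {
  require_columns(cohort_a, variable)
  require_columns(cohort_b, variable)
  a <- cohort_a[[variable]]
  b <- cohort_b[[variable]]
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) == 0L || length(b) == 0L) stop("empty cohort")
  ks <- suppressWarnings(stats::ks.test(a, b))
  data.frame(variable = variable, statistic = unname(ks$statistic),
             p_value = ks$p.value, stringsAsFactors = FALSE)
}
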