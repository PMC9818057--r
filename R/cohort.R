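#' @keywords internal
"_PACKAGE"

core_variables <- c("age", "gender", "cfs", "sofa")
geriatric_variables <- c("comorbidities", "katz", "residence")

cohort_columns <- c("study_id", "age", "gender", "cfs", "sofa",
                    "admission_type", "withhold", "withdraw", "los_days",
                    "country", "comorbidities", "katz", "residence")

require_columns <- function(cohort, cols) {
  missing <- setdiff(cols, names(cohort))
  if (length(missing)) {
    stop("cohort is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
}

#' Restrict a cohort to non-elective admissions with complete core data
#'
#' Inclusion step applied before any information analysis: keeps only
#' patients with a non-elective ICU admission and no missing value among the
#' four core characteristics (age, gender, CFS, SOFA).  Row order is
#' preserved and the number of exclusions per reason is reported via
#' `message()`.
#'
#' @param cohort A cohort data frame (see [generate_cohort()] for the
#'   schema).
#' @return The filtered cohort.
#' @examples
#' coh <- generate_cohort(cohort_spec(n_patients = 200, seed = 1),
#'                        mechanism_null())
#' nrow(apply_filters(coh))
#' @export
apply_filters <- function(cohort) {
  require_columns(cohort, c("admission_type", core_variables))
  if (nrow(cohort) == 0L) return(cohort)
  elective <- !is.na(cohort$admission_type) &
    cohort$admission_type == "elective"
  incomplete <- Reduce(`|`, lapply(cohort[core_variables], is.na)) |
    is.na(cohort$admission_type)
  message(sum(elective), " elective admission(s) and ",
          sum(incomplete & !elective),
          " row(s) with incomplete core data excluded (",
          sum(!(elective | incomplete)), " retained)")
  cohort[!(elective | incomplete), , drop = FALSE]
}

#' Extract the geriatric subgroup with near-complete geriatric data
#'
#' Retains patients with less than 20% missing data across the three
#' geriatric variables (number of comorbidities, Katz index, residence prior
#' to hospital admission).  With three variables, one missing value already
#' amounts to 1/3 >= 20%, so exactly the rows with all three present are
#' kept.
#'
#' @param cohort A cohort data frame carrying the geriatric columns.
#' @return The subgroup cohort.
#' @export
geriatric_subgroup <- function(cohort) {
  require_columns(cohort, geriatric_variables)
  if (nrow(cohort) == 0L) return(cohort)
  n_missing <- Reduce(`+`, lapply(cohort[geriatric_variables],
                                  function(x) as.integer(is.na(x))))
  keep <- n_missing / length(geriatric_variables) < 0.20
  message(sum(!keep), " row(s) excluded from geriatric subgroup (",
          sum(keep), " retained)")
  cohort[keep, , drop = FALSE]
}

#' Validate a cohort table against the schema
#'
#' Checks column presence, value domains (age >= 80, CFS in 1..9, SOFA in
#' 0..24, Katz in 0..6, nonnegative length of stay) and the categorical
#' levels for gender, admission type and residence.  Missing values are
#' permitted everywhere except the decision flags.
#'
#' @param cohort A cohort data frame.
#' @return `cohort`, invisibly, if valid; otherwise an error.
#' @export
validate_cohort <- function(cohort) {
  require_columns(cohort, setdiff(cohort_columns, geriatric_variables))
  chk <- function(ok, what) {
    if (!all(ok, na.rm = TRUE)) stop("invalid cohort: ", what)
  }
  chk(cohort$age >= 80, "age below 80")
  chk(cohort$cfs >= 1 & cohort$cfs <= 9, "CFS outside 1..9")
  chk(cohort$sofa >= 0 & cohort$sofa <= 24, "SOFA outside 0..24")
  chk(cohort$los_days >= 0, "negative length of stay")
  chk(cohort$gender %in% c("female", "male"), "unknown gender level")
  chk(cohort$admission_type %in% c("elective", "non_elective"),
      "unknown admission type")
  chk(cohort$withhold %in% c(TRUE, FALSE) & !is.na(cohort$withhold),
      "withhold flag missing or non-boolean")
  chk(cohort$withdraw %in% c(TRUE, FALSE) & !is.na(cohort$withdraw),
      "withdraw flag missing or non-boolean")
  if ("katz" %in% names(cohort)) {
    chk(cohort$katz >= 0 & cohort$katz <= 6, "Katz index outside 0..6")
  }
  if ("residence" %in% names(cohort)) {
    chk(cohort$residence %in% c("home", "home_with_caregiver",
                                "nursing_home_or_hospital", "other"),
        "unknown residence level")
  }
  invisible(cohort)
}

#' Write a cohort table to CSV
#'
#' UTF-8 CSV with the documented schema header; missing values are encoded
#' as empty fields.  Optionally emits a provenance sidecar
#' (`<path>.provenance.json`) recording the generator seed and settings when
#' the cohort carries them as attributes.
#'
#' @param cohort A cohort data frame.
#' @param path Output file path.
#' @param provenance Write the sidecar if generation metadata is attached?
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, provenance = TRUE) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  prov <- attr(cohort, "provenance")
  if (provenance && !is.null(prov)) {
    jsonlite::write_json(prov, paste0(path, ".provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' Inverse of [write_cohort()]: empty fields become `NA`, decision flags are
#' logical, characteristics numeric, grouping keys character.
#'
#' @param path CSV file path.
#' @return A cohort data frame.
#' @export
read_cohort <- function(path) {
  coh <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  for (col in intersect(c("withhold", "withdraw"), names(coh))) {
    coh[[col]] <- as.logical(coh[[col]])
  }
  for (col in intersect(c("age", "cfs", "sofa", "comorbidities", "katz",
                          "los_days"), names(coh))) {
    coh[[col]] <- as.numeric(coh[[col]])
  }
  coh
}
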