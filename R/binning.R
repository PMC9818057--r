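#' Binning scheme for patient characteristics
#'
#' Fixed mapping from raw characteristic values to ordered categories:
#' age in 2-year bins from 80 (80-81, 82-83, ..., 94-95; older than 95 in the
#' terminal bin 8); CFS one category per bin with CFS 9 absorbed into bin 8;
#' SOFA in 2-point bins from 0 (0-1, ..., 14-15; above 15 in bin 8);
#' comorbidity counts one per bin from 0 with counts above 7 in bin 8; Katz
#' index 0-6 giving 7 bins; gender 2 categories; residence prior to hospital
#' admission 4 categories.  Each interval variable has a designated terminal
#' bin absorbing out-of-range-high values; values below the domain floor are
#' an error.
#'
#' @param ... Named per-variable overrides, each a list with either
#'   `type = "interval"` (`origin`, `width`, `n_bins`) or
#'   `type = "categorical"` (`levels`), replacing or extending the defaults.
#' @return An object of class `binning_scheme`: a named list of bin
#'   definitions.
#' @examples
#' sch <- binning_scheme()
#' scheme_n_bins(sch, "age")
#' @export
binning_scheme <- function(...) {
  scheme <- list(
    age           = list(type = "interval", origin = 80, width = 2, n_bins = 8L),
    cfs           = list(type = "interval", origin = 1,  width = 1, n_bins = 8L),
    sofa          = list(type = "interval", origin = 0,  width = 2, n_bins = 8L),
    comorbidities = list(type = "interval", origin = 0,  width = 1, n_bins = 8L),
    katz          = list(type = "interval", origin = 0,  width = 1, n_bins = 7L),
    gender        = list(type = "categorical", levels = c("female", "male")),
    residence     = list(type = "categorical",
                         levels = c("home", "home_with_caregiver",
                                    "nursing_home_or_hospital", "other"))
  )
  overrides <- list(...)
  for (nm in names(overrides)) scheme[[nm]] <- overrides[[nm]]
  structure(scheme, class = "binning_scheme")
}

scheme_entry <- function(scheme, variable) {
  entry <- scheme[[variable]]
  if (is.null(entry)) {
    stop("no binning rule for variable '", variable, "'")
  }
  entry
}

#' Number of bins a scheme assigns to a variable
#'
#' @param scheme A [binning_scheme].
#' @param variable Variable name.
#' @return Integer bin count (the `N` entering entropy and predictability).
#' @export
scheme_n_bins <- function(scheme, variable) {
  entry <- scheme_entry(scheme, variable)
  if (entry$type == "interval") as.integer(entry$n_bins)
  else length(entry$levels)
}

#' Bin raw characteristic values into ordered categories
#'
#' Maps raw values to 1-based bin indices under the scheme's rule for the
#' variable.  Missing values pass through as `NA`; values above the interval
#' domain are absorbed by the terminal bin; values below the domain floor
#' (e.g. age 79 in a cohort restricted to 80+) raise an error naming the
#' offending value.
#'
#' @param values Raw values (numeric for interval variables, character or
#'   factor for categorical ones).
#' @param variable Variable name known to the scheme.
#' @param scheme A [binning_scheme]; defaults to the standard scheme.
#' @return Integer vector of bin indices in `1..n_bins`, same length and
#'   order as `values`.
#' @examples
#' bin_variable(c(80, 81, 95, 97), "age") # 1 1 8 8
#' bin_variable(c(1, 8, 9), "cfs")        # 1 8 8
#' @export
bin_variable <- function(values, variable, scheme = binning_scheme()) {
  entry <- scheme_entry(scheme, variable)
  if (entry$type == "interval") {
    values <- as.numeric(values)
    bad <- !is.na(values) & values < entry$origin
    if (any(bad)) {
      stop("value ", values[which(bad)[1]], " of '", variable,
           "' is below the domain floor ", entry$origin)
    }
    idx <- floor((values - entry$origin) / entry$width) + 1
    as.integer(pmin(idx, entry$n_bins))
  } else {
    values <- as.character(values)
    idx <- match(values, entry$levels)
    bad <- !is.na(values) & is.na(idx)
    if (any(bad)) {
      stop("unknown category '", values[which(bad)[1]], "' for '", variable,
           "'; expected one of: ", paste(entry$levels, collapse = ", "))
    }
    as.integer(idx)
  }
}

#' Human-readable labels for a variable's bins
#'
#' @inheritParams scheme_n_bins
#' @return Character vector of length `scheme_n_bins(scheme, variable)`.
#' @export
bin_labels <- function(scheme, variable) {
  entry <- scheme_entry(scheme, variable)
  if (entry$type == "categorical") return(entry$levels)
  lo <- entry$origin + (seq_len(entry$n_bins) - 1) * entry$width
  hi <- lo + entry$width - 1
  lab <- if (entry$width == 1) as.character(lo) else paste0(lo, "-", hi)
  lab[entry$n_bins] <- paste0(">=", lo[entry$n_bins])
  lab
}

#' Serialise a binning scheme to YAML
#'
#' @param scheme A [binning_scheme].
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_binning_scheme <- function(scheme, path) {
  yaml::write_yaml(unclass(scheme), path)
  invisible(path)
}

#' Read a binning scheme from YAML
#'
#' @param path File written by [write_binning_scheme()].
#' @return A [binning_scheme].
#' @export
read_binning_scheme <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(binning_scheme, raw)
}
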