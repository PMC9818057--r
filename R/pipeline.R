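#' Configuration of an end-to-end analysis run
#'
#' Bundles every tunable of the pipeline: the input cohort (path to a CSV
#' or an in-memory data frame), the binning scheme, which decision types to
#' analyse, bootstrap settings, the pseudo-count, the frailty threshold and
#' minimal-length-of-stay grid for the stay-stratified subanalysis, the
#' grouping key and minimal group size for the per-country subanalysis, and
#' the output directory.
#'
#' @param input Path to a cohort CSV (see [read_cohort()]) or a cohort data
#'   frame.
#' @param output_dir Directory for report files, or `NULL` to skip writing.
#' @param decisions Decision types to analyse.
#' @param variables Characteristics to analyse; `NULL` selects every
#'   schema characteristic present in the input.
#' @param bootstrap_reps Bootstrap replicates, `>= 2` (default 100).
#' @param seed Integer seed for all resampling.
#' @param pseudo Nonnegative pseudo-count for likelihood and divergence
#'   cells.
#' @param frailty_threshold Minimal CFS defining frailty.
#' @param mlos_grid Strictly increasing minimal-length-of-stay thresholds.
#' @param group_key Grouping column for [grouped_information()].
#' @param min_group_size Minimal group size (default 500).
#' @param geriatric Also restrict to the geriatric subgroup first?
#' @param scheme A [binning_scheme].
#' @return An object of class `run_config`.
#' @export
run_config <- function(input, output_dir = NULL,
                       decisions = c("withhold", "withdraw"),
                       variables = NULL, bootstrap_reps = 100, seed = 1L,
                       pseudo = 0.5, frailty_threshold = 4,
                       mlos_grid = c(0, 2, 4, 6, 8, 10),
                       group_key = "country", min_group_size = 500,
                       geriatric = FALSE, scheme = binning_scheme()) {
  if (bootstrap_reps < 2) stop("bootstrap_reps must be at least 2")
  if (pseudo < 0) stop("pseudo must be nonnegative")
  if (any(mlos_grid < 0) || is.unsorted(mlos_grid, strictly = TRUE)) {
    stop("mlos_grid must be nonnegative and strictly increasing")
  }
  decisions <- match.arg(decisions, several.ok = TRUE)
  structure(list(input = input, output_dir = output_dir,
                 decisions = decisions, variables = variables,
                 bootstrap_reps = bootstrap_reps, seed = as.integer(seed),
                 pseudo = pseudo, frailty_threshold = frailty_threshold,
                 mlos_grid = mlos_grid, group_key = group_key,
                 min_group_size = min_group_size, geriatric = geriatric,
                 scheme = scheme),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full decision-information pipeline
#'
#' Executes the analysis sequence end to end: inclusion filters (non-
#' elective admissions with complete core data, optionally the geriatric
#' subgroup), binning, per-variable and per-decision information summaries
#' with bootstrap standard deviations, pre/post-decision divergences with
#' AUROC, multivariable logistic regression, the frail-patient
#' length-of-stay stratification, and (when any group is large enough) the
#' per-group comparison.  Writes machine-readable (JSON) and formatted
#' (CSV) tables plus a provenance record, and is deterministic given the
#' same configuration and seed.  On failure, partially written outputs are
#' removed.
#'
#' @param config A [run_config].
#' @return An object of class `lst_report`: a list with elements
#'   `exclusions`, `summaries` (per decision x variable), `regression`,
#'   `stratified`, `grouped`, `config_echo`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cohort <- stage("read", {
    if (is.character(config$input)) read_cohort(config$input)
    else config$input
  })
  n_input <- nrow(cohort)
  included <- stage("filters", suppressMessages(apply_filters(cohort)))
  if (config$geriatric) {
    included <- stage("geriatric_subgroup",
                      suppressMessages(geriatric_subgroup(included)))
  }
  vars <- config$variables
  if (is.null(vars)) {
    vars <- intersect(c(core_variables, geriatric_variables),
                      names(included))
    vars <- vars[vapply(vars, function(v) !all(is.na(included[[v]])),
                        logical(1))]
  }

  summaries <- stage("information", {
    rows <- list()
    for (dec in config$decisions) {
      for (v in vars) {
        rows[[length(rows) + 1L]] <-
          variable_summary(included, v, dec, config$scheme, config$pseudo,
                           n_reps = config$bootstrap_reps,
                           seed = config$seed)
      }
    }
    do.call(rbind, rows)
  })

  regression <- stage("regression", {
    out <- lapply(config$decisions, function(dec) {
      fit_decision_regression(included, vars, dec, config$scheme)
    })
    names(out) <- config$decisions
    out
  })

  stratified <- stage("los_stratification", {
    out <- lapply(config$decisions, function(dec) {
      los_stratified_information(included, config$frailty_threshold,
                                 config$mlos_grid,
                                 intersect(c("age", "cfs", "sofa"), vars),
                                 dec, config$scheme, config$pseudo)
    })
    names(out) <- config$decisions
    out
  })

  grouped <- stage("grouped", {
    sizes <- table(included[[config$group_key]])
    if (any(sizes >= config$min_group_size)) {
      out <- lapply(config$decisions, function(dec) {
        suppressMessages(grouped_information(
          included, config$group_key, config$min_group_size,
          intersect(core_variables, vars), dec, config$scheme,
          config$pseudo, n_reps = config$bootstrap_reps,
          seed = config$seed))
      })
      names(out) <- config$decisions
      out
    } else NULL
  })

  report <- structure(
    list(exclusions = list(n_input = n_input, n_included = nrow(included)),
         summaries = summaries, regression = regression,
         stratified = stratified, grouped = grouped,
         config_echo = list(decisions = config$decisions, variables = vars,
                            bootstrap_reps = config$bootstrap_reps,
                            seed = config$seed, pseudo = config$pseudo,
                            frailty_threshold = config$frailty_threshold,
                            mlos_grid = config$mlos_grid,
                            min_group_size = config$min_group_size,
                            geriatric = config$geriatric)),
    class = "lst_report")

  if (!is.null(config$output_dir)) {
    written <- character(0)
    tryCatch({
      dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
      path <- function(f) file.path(config$output_dir, f)
      jsonlite::write_json(unclass_report(report), path("report.json"),
                           auto_unbox = TRUE, digits = NA, na = "null")
      written <- c(written, path("report.json"))
      jsonlite::write_json(
        c(report$config_echo,
          list(package_version =
                 as.character(utils::packageVersion("lstentropy")),
               r_version = paste(R.version$major, R.version$minor,
                                 sep = "."),
               n_input = n_input, n_included = nrow(included))),
        path("provenance.json"), auto_unbox = TRUE, digits = NA)
      written <- c(written, path("provenance.json"))
      written <- c(written, render_tables(report, config$output_dir))
    }, error = function(e) {
      unlink(written)
      stop("stage 'write': ", conditionMessage(e), call. = FALSE)
    })
  }
  report
}

unclass_report <- function(report) {
  strip <- function(x) {
    if (is.data.frame(x)) as.data.frame(lapply(x, unclass))
    else if (is.list(x)) lapply(x, strip)
    else x
  }
  strip(unclass(report))
}

#' Check an analysis report for structural completeness
#'
#' Verifies that a report (or its JSON round-trip) carries the expected
#' sections and that every reported entropy respects its maximum.
#'
#' @param report An `lst_report` or the list read back from `report.json`.
#' @return `TRUE` invisibly, or an error.
#' @export
validate_report <- function(report) {
  needed <- c("exclusions", "summaries", "regression", "stratified",
              "config_echo")
  missing <- setdiff(needed, names(report))
  if (length(missing)) {
    stop("report is missing section(s): ", paste(missing, collapse = ", "))
  }
  s <- report$summaries
  if (is.data.frame(s) &&
      any(s$entropy_bits > s$h_max_bits + 1e-9, na.rm = TRUE)) {
    stop("report contains an entropy above its maximum")
  }
  invisible(TRUE)
}

fmt_mean <- function(x, digits = 2) {
  s <- sprintf(paste0("%.", digits, "f"), x)
  ifelse(grepl("0$", s) & grepl("\\.", s), sub("0$", "", s), s)
}

fmt_sd <- function(x) {
  format(signif(x, 1), scientific = FALSE, trim = TRUE)
}

fmt_pm <- function(mean, sd, digits = 2) {
  ifelse(is.na(mean), "NA", paste0(fmt_mean(mean, digits), " ± ",
                                   fmt_sd(sd)))
}

#' Render formatted result tables
#'
#' Writes publication-style CSV tables from a pipeline report: the entropy
#' table ("mean ± SD" per variable and decision, with the regression odds
#' ratio and 95% confidence interval in brackets), the divergence table
#' (D_KL ± SD with the AUROC in brackets), and one entropy-by-minimal-
#' length-of-stay table per decision.  Entropies and predictabilities are
#' rounded to 2 decimals, divergences to 2 significant figures, standard
#' deviations to 1 significant figure, without scientific notation; empty
#' strata render as `NA`, never as 0.
#'
#' @param report An `lst_report`.
#' @param output_dir Directory to write into.
#' @return Character vector of the files written, invisibly.
#' @export
render_tables <- function(report, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  s <- report$summaries
  decisions <- unique(s$decision)

  or_bracket <- function(dec, var) {
    reg <- report$regression[[dec]]
    if (is.null(reg)) return("")
    hit <- reg[startsWith(reg$term, var), , drop = FALSE]
    if (nrow(hit) == 0L) return("")
    paste(sprintf("(%s, %s-%s)", fmt_mean(hit$or), fmt_mean(hit$ci_low),
                  fmt_mean(hit$ci_high)), collapse = " ")
  }

  ent <- data.frame(variable = unique(s$variable),
                    h_max = fmt_mean(s$h_max_bits[!duplicated(s$variable)], 1),
                    stringsAsFactors = FALSE)
  div <- data.frame(variable = unique(s$variable), stringsAsFactors = FALSE)
  for (dec in decisions) {
    sd_ <- s[s$decision == dec, ]
    m <- match(ent$variable, sd_$variable)
    ent[[dec]] <- paste(fmt_pm(sd_$entropy_mean[m], sd_$entropy_sd[m]),
                        vapply(ent$variable, or_bracket, "", dec = dec))
    div[[dec]] <- sprintf("%s ± %s (%s)",
                          format(signif(sd_$d_kl_bits[m], 2),
                                 scientific = FALSE, trim = TRUE),
                          fmt_sd(sd_$d_kl_sd[m]),
                          fmt_mean(sd_$auroc[m]))
  }
  f <- file.path(output_dir, "entropy_table.csv")
  utils::write.csv(ent, f, row.names = FALSE)
  written <- c(written, f)
  f <- file.path(output_dir, "divergence_table.csv")
  utils::write.csv(div, f, row.names = FALSE)
  written <- c(written, f)

  for (dec in names(report$stratified %||% list())) {
    st <- report$stratified[[dec]]
    wide <- stats::reshape(
      st[, c("mlos", "variable", "entropy_bits")], direction = "wide",
      idvar = "mlos", timevar = "variable")
    names(wide) <- sub("^entropy_bits\\.", "", names(wide))
    f <- file.path(output_dir, paste0("stratified_", dec, ".csv"))
    utils::write.csv(wide, f, row.names = FALSE)
    written <- c(written, f)
  }
  invisible(written)
}
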