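# Cohort accounting and the end-to-end pipeline front end.

#' Cohort accounting
#'
#' Tracks the flow from enrollment to analysis: enrolled patients,
#' exclusions by reason (patients ending with zero valid measurement days),
#' the analyzed count and the count with usable POD1 physical-activity data.
#' All percentages are recomputed from the counts, never stored.
#'
#' @param n_enrolled Number of patients enrolled.
#' @param exclusions Named integer vector of exclusion counts by reason
#'   (e.g. \code{c(delayed_fixation = 5, early_discharge = 1,
#'   malfunction = 3)}).
#' @param n_with_pod1 Number of analyzed patients with a valid POD1 day.
#' @return A list of class \code{cohort_accounting} with \code{n_enrolled},
#'   \code{exclusions}, \code{n_analyzed}, \code{pct_analyzed},
#'   \code{n_with_pod1}, \code{pct_with_pod1}.
#' @export
cohort_accounting <- function(n_enrolled, exclusions = integer(0),
                              n_with_pod1 = NA_integer_) {
  n_excl <- sum(exclusions)
  n_analyzed <- n_enrolled - n_excl
  if (n_analyzed < 0) stop_input("exclusions exceed enrollment")
  if (!is.na(n_with_pod1) && n_with_pod1 > n_analyzed) {
    stop_input("n_with_pod1 cannot exceed n_analyzed")
  }
  structure(list(
    n_enrolled = n_enrolled, exclusions = exclusions,
    n_excluded = n_excl,
    pct_excluded = 100 * n_excl / n_enrolled,
    n_analyzed = n_analyzed,
    pct_analyzed = 100 * n_analyzed / n_enrolled,
    n_with_pod1 = n_with_pod1,
    pct_with_pod1 = if (is.na(n_with_pod1)) NA_real_ else
      100 * n_with_pod1 / n_analyzed),
    class = "cohort_accounting")
}

#' @export
print.cohort_accounting <- function(x, ...) {
  cat(sprintf("Enrolled: %d\n", x$n_enrolled))
  for (r in names(x$exclusions)) {
    cat(sprintf("  excluded (%s): %d\n", r, x$exclusions[[r]]))
  }
  cat(sprintf("Analyzed: %d (%.1f%%)\n", x$n_analyzed, x$pct_analyzed))
  if (!is.na(x$n_with_pod1)) {
    cat(sprintf("With valid POD1 activity data: %d (%.1f%% of analyzed)\n",
                x$n_with_pod1, x$pct_with_pod1))
  }
  invisible(x)
}

# Accounting derived from a simulated cohort's own records.
accounting_from_cohort <- function(cohort) {
  pats <- cohort$patients
  daily <- cohort$daily
  valid_ids <- unique(daily$patient_id[daily$valid])
  excluded <- pats[!pats$patient_id %in% valid_ids, , drop = FALSE]
  reasons <- table(factor(
    ifelse(is.na(excluded$excluded_reason), "other", excluded$excluded_reason)))
  pod1_ids <- unique(daily$patient_id[daily$valid & daily$pod == 1])
  cohort_accounting(nrow(pats),
                    setNames(as.integer(reasons), names(reasons)),
                    n_with_pod1 = length(intersect(pod1_ids, valid_ids)))
}

#' Run the full analysis pipeline
#'
#' One deterministic pass from data to report: obtain the analysis table
#' (either simulated under \code{config$simulation}, or assembled from
#' supplied daily-summary, patient and mILAS tables), compute the cohort
#' accounting, group descriptives, the crude and confounder-adjusted linear
#' model for POD1 active minutes, and the crude and adjusted logistic model
#' for functional recovery on POD1, each with its change-in-estimate
#' selection trace. Every stage's parameters are echoed into the report's
#' \code{log} so a run is self-describing.
#'
#' @param config A \code{\link{pipeline_config}} (or list of overrides).
#' @param daily,patients,milas Optional input tables; when all are supplied
#'   simulation is skipped.
#' @param surgery_dates Surgery date(s) for mILAS POD indexing when real
#'   tables are supplied.
#' @return A list of class \code{pipeline_report}: \code{accounting},
#'   \code{descriptives}, \code{linear} and \code{logistic} (each a
#'   \code{cie_selection} with crude fit, final fit and trace), \code{log}.
#' @export
run_pipeline <- function(config = pipeline_config(), daily = NULL,
                         patients = NULL, milas = NULL,
                         surgery_dates = NULL) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  log_lines <- c(
    sprintf("seed: %d", config$seed),
    sprintf("classifier: dynamic_threshold_g=%.3g orientation_cutoff_g=%.3g axis=%s noise_cutoff_hz=%.3g min_window_samples=%d",
            config$classifier$dynamic_threshold_g,
            config$classifier$orientation_cutoff_g,
            config$classifier$longitudinal_axis,
            config$classifier$noise_cutoff_hz,
            config$classifier$min_window_samples),
    sprintf("summary: valid_day_threshold_h=%.3g tz=%s",
            config$summary$valid_day_threshold_h, config$tz),
    sprintf("analysis: main=%s candidates=%s cie_threshold_pct=%.3g sig_level=%.3g",
            config$analysis$main,
            paste(config$analysis$candidates, collapse = ","),
            config$analysis$cie_threshold_pct, config$analysis$sig_level))

  have_inputs <- !is.null(daily) && !is.null(patients)
  if (have_inputs) {
    log_lines <- c(log_lines, "inputs: user-supplied tables")
    valid_ids <- unique(daily$patient_id[daily$valid])
    tab <- patients[patients$patient_id %in% valid_ids, , drop = FALSE]
    pod1 <- select_analysis_days(
      daily[daily$patient_id %in% valid_ids, , drop = FALSE], pod = 1)
    tab$active_min_pod1 <- pod1$active_min[match(tab$patient_id,
                                                 pod1$patient_id)]
    if (!is.null(milas)) {
      rec <- recovery_endpoint(milas, surgery_dates)
      tab$recovered_on_pod1 <- rec$recovered_on_pod1[
        match(tab$patient_id, rec$patient_id)]
    }
    excluded <- patients[!patients$patient_id %in% valid_ids, , drop = FALSE]
    reasons <- if ("excluded_reason" %in% names(excluded)) {
      tb <- table(ifelse(is.na(excluded$excluded_reason), "other",
                         excluded$excluded_reason))
      setNames(as.integer(tb), names(tb))
    } else c(other = nrow(excluded))
    accounting <- cohort_accounting(
      nrow(patients), reasons,
      n_with_pod1 = sum(!is.na(tab$active_min_pod1)))
  } else {
    if (!isTRUE(config$simulation$enabled)) {
      stop_input("config error: no input tables and simulation disabled")
    }
    log_lines <- c(log_lines, "inputs: simulated cohort")
    cohort <- simulate_cohort(cohort_params(seed = config$seed))
    tab <- analysis_table(cohort)
    accounting <- accounting_from_cohort(cohort)
  }

  if (!all(c(0, 1) %in% tab[[config$analysis$main]])) {
    stop_input("single-class error: both treatment groups must be present")
  }

  descr_vars <- intersect(c("age", "sex", "bmi", "surgery", "asa_high",
                            "los_days", "active_min_pod1"), names(tab))
  descriptives <- describe_cohort(tab[c(config$analysis$main, descr_vars)],
                                  group = config$analysis$main)

  linear <- select_confounders(
    tab, outcome = config$analysis$outcome_linear,
    main = config$analysis$main,
    candidates = config$analysis$candidates, model_type = "linear",
    threshold = config$analysis$cie_threshold_pct)
  logistic <- if (config$analysis$outcome_logistic %in% names(tab) &&
                  sum(!is.na(tab[[config$analysis$outcome_logistic]])) > 0) {
    select_confounders(
      tab, outcome = config$analysis$outcome_logistic,
      main = config$analysis$main,
      candidates = config$analysis$candidates, model_type = "logistic",
      threshold = config$analysis$cie_threshold_pct)
  } else NULL

  structure(list(accounting = accounting, descriptives = descriptives,
                 linear = linear, logistic = logistic,
                 analysis_table = tab, config = config, log = log_lines),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("== Pipeline report ==\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n\n")
  print(x$accounting)
  cat("\n-- Linear model: POD1 active minutes --\n")
  print(x$linear)
  if (!is.null(x$logistic)) {
    cat("\n-- Logistic model: functional recovery on POD1 --\n")
    print(x$logistic)
  }
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Emits the report as CSV tables (descriptives, model terms, selection
#' traces, accounting) plus a human-readable \code{report.txt}, all under
#' one directory.
#'
#' @param report A \code{pipeline_report}.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  acc <- report$accounting
  acc_df <- data.frame(
    metric = c("n_enrolled", paste0("excluded_", names(acc$exclusions)),
               "n_analyzed", "pct_analyzed", "n_with_pod1", "pct_with_pod1"),
    value = c(acc$n_enrolled, as.numeric(acc$exclusions), acc$n_analyzed,
              acc$pct_analyzed, acc$n_with_pod1, acc$pct_with_pod1))
  write.csv(acc_df, file.path(dir, "accounting.csv"), row.names = FALSE)
  write.csv(report$descriptives, file.path(dir, "descriptives.csv"),
            row.names = FALSE)
  write.csv(report$linear$crude$terms, file.path(dir, "linear_crude.csv"),
            row.names = FALSE)
  write.csv(report$linear$final$terms, file.path(dir, "linear_final.csv"),
            row.names = FALSE)
  write.csv(report$linear$trace, file.path(dir, "linear_selection_trace.csv"),
            row.names = FALSE)
  if (!is.null(report$logistic)) {
    write.csv(report$logistic$crude$terms,
              file.path(dir, "logistic_crude.csv"), row.names = FALSE)
    write.csv(report$logistic$final$terms,
              file.path(dir, "logistic_final.csv"), row.names = FALSE)
    write.csv(report$logistic$trace,
              file.path(dir, "logistic_selection_trace.csv"),
              row.names = FALSE)
  }
  txt <- file.path(dir, "report.txt")
  con <- file(txt, open = "wt")
  sink(con); on.exit({ sink(); close(con) })
  print(report)
  invisible(dir)
}
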