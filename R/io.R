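# CSV interchange and pipeline configuration. All tabular I/O is headered
# CSV with ISO-8601 timestamps; every writer's output round-trips through
# its reader.

fmt_time <- function(x) format(x, "%Y-%m-%dT%H:%M:%OS3", tz = attr(x, "tzone") %||% "UTC")

parse_time <- function(x, tz = "UTC") {
  as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%OS", tz = tz)
}

#' Read / write signal, schedule, patient, minute, daily and mILAS CSVs
#'
#' The interchange formats of the pipeline:
#' \itemize{
#'   \item signal: \code{timestamp_iso8601,x_g,y_g,z_g}, one row per sample;
#'   \item schedule: \code{patient_id,start_iso8601,duration_s,posture};
#'   \item patient: \code{patient_id,group,age,sex,bmi,surgery,asa_class,
#'     los_days};
#'   \item minute: \code{minute_start,sedentary_s,standing_s,dynamic_s,
#'     covered_s};
#'   \item daily: \code{patient_id,date,pod,wear_h,valid,active_min,
#'     sedentary_min};
#'   \item mILAS: \code{patient_id,timestamp,supine_to_sit,sit_to_supine,
#'     sit_to_stand,walking,stairs,needs_stairs_at_home}.
#' }
#'
#' @param path File path.
#' @param signal,minutes,daily,patients,milas,schedule The corresponding
#'   data.frames.
#' @param tz Timezone applied when parsing timestamps.
#' @param sample_rate_hz Nominal rate attached to a read signal.
#' @name actiward-io
NULL

#' @rdname actiward-io
#' @export
write_signal_csv <- function(signal, path) {
  out <- data.frame(timestamp_iso8601 = fmt_time(signal$time),
                    x_g = signal$x_g, y_g = signal$y_g, z_g = signal$z_g)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname actiward-io
#' @export
read_signal_csv <- function(path, tz = "UTC", sample_rate_hz = 25) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  assert_columns(df, c("timestamp_iso8601", "x_g", "y_g", "z_g"),
                 basename(path))
  out <- data.frame(time = parse_time(df$timestamp_iso8601, tz),
                    x_g = df$x_g, y_g = df$y_g, z_g = df$z_g)
  attr(out, "sample_rate_hz") <- sample_rate_hz
  class(out) <- c("raw_signal", "data.frame")
  out
}

#' @rdname actiward-io
#' @export
write_schedule_csv <- function(schedule, path, patient_id = NA_character_) {
  out <- data.frame(patient_id = patient_id,
                    start_iso8601 = fmt_time(schedule$start_time),
                    duration_s = schedule$duration_s,
                    posture = schedule$posture)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname actiward-io
#' @export
read_schedule_csv <- function(path, tz = "UTC") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  assert_columns(df, c("start_iso8601", "duration_s", "posture"),
                 basename(path))
  sch <- posture_schedule(parse_time(df$start_iso8601, tz), df$duration_s,
                          df$posture, tz = tz)
  sch$patient_id <- df$patient_id %||% NA_character_
  sch
}

#' @rdname actiward-io
#' @export
write_minutes_csv <- function(minutes, path) {
  out <- minutes
  out$minute_start <- fmt_time(out$minute_start)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname actiward-io
#' @export
read_minutes_csv <- function(path, tz = "UTC") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  assert_columns(df, c("minute_start", "sedentary_s", "standing_s",
                       "dynamic_s", "covered_s"), basename(path))
  df$minute_start <- parse_time(df$minute_start, tz)
  df
}

#' @rdname actiward-io
#' @export
write_daily_csv <- function(daily, path) {
  write.csv(daily, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname actiward-io
#' @export
read_daily_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  assert_columns(df, c("patient_id", "date", "pod", "wear_h", "valid",
                       "active_min"), basename(path))
  df$date <- as.Date(df$date)
  df$valid <- as.logical(df$valid)
  df
}

#' @rdname actiward-io
#' @export
write_patients_csv <- function(patients, path) {
  write.csv(patients, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname actiward-io
#' @export
read_patients_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  assert_columns(df, c("patient_id", "group", "age", "sex", "bmi",
                       "surgery"), basename(path))
  df
}

#' @rdname actiward-io
#' @export
write_milas_csv <- function(milas, path) {
  out <- milas
  out$timestamp <- fmt_time(out$timestamp)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname actiward-io
#' @export
read_milas_csv <- function(path, tz = "UTC") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  assert_columns(df, c("patient_id", "timestamp", MILAS_ITEMS,
                       "needs_stairs_at_home"), basename(path))
  df$timestamp <- parse_time(df$timestamp, tz)
  df$needs_stairs_at_home <- as.logical(df$needs_stairs_at_home)
  df
}

# ---- pipeline configuration ----

pipeline_config_defaults <- function() {
  list(
    seed = 1L,
    tz = "UTC",
    classifier = list(dynamic_threshold_g = 0.1, orientation_cutoff_g = 0.8,
                      longitudinal_axis = "z", noise_cutoff_hz = 5,
                      min_window_samples = 20),
    summary = list(valid_day_threshold_h = 20),
    analysis = list(main = "group", outcome_linear = "active_min_pod1",
                    outcome_logistic = "recovered_on_pod1",
                    candidates = c("age", "sex", "bmi", "surgery", "asa_high"),
                    cie_threshold_pct = 10, sig_level = 0.05),
    simulation = list(enabled = TRUE))
}

#' Build and validate a pipeline configuration
#'
#' Merges user settings (an R list or a YAML file) over the package
#' defaults. Unknown keys at any level are rejected, so typos fail loudly
#' before any computation; every threshold in the configuration is echoed
#' into the run log by \code{\link{run_pipeline}}.
#'
#' @param config A named list of overrides, or \code{NULL} for defaults.
#' @param yaml_file Optional path to a YAML file of overrides.
#' @return A validated configuration list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(config = NULL, yaml_file = NULL) {
  defaults <- pipeline_config_defaults()
  if (!is.null(yaml_file)) {
    config <- modifyList(yaml::read_yaml(yaml_file), config %||% list())
  }
  config <- config %||% list()
  check_keys <- function(user, ref, path = "") {
    unknown <- setdiff(names(user), names(ref))
    if (length(unknown)) {
      stop_input("config error: unknown key(s): ",
                 paste0(path, unknown, collapse = ", "))
    }
    for (k in names(user)) {
      if (is.list(ref[[k]]) && !is.null(names(ref[[k]]))) {
        check_keys(as.list(user[[k]]), ref[[k]], paste0(path, k, "."))
      }
    }
  }
  check_keys(config, defaults)
  merged <- modifyList(defaults, config)
  # validate by constructing the component configs
  do.call(classifier_config, merged$classifier)
  summary_config(merged$summary$valid_day_threshold_h, merged$tz)
  structure(merged, class = c("pipeline_config", "list"))
}
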