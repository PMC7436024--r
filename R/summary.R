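# Daily summaries of the primary outcome: minutes standing and walking per
# day, with wear-time validity and postoperative-day indexing.

#' Summary configuration
#'
#' @param valid_day_threshold_h Hours of wear needed for a valid measurement
#'   day; default 20 (the boundary is inclusive: exactly 20 h is valid).
#' @param tz Timezone defining the local-midnight day boundary.
#' @return A list of class \code{summary_config}.
#' @export
summary_config <- function(valid_day_threshold_h = 20, tz = "UTC") {
  if (!is.numeric(valid_day_threshold_h) || valid_day_threshold_h <= 0 ||
      valid_day_threshold_h > 24) {
    stop_input("valid_day_threshold_h must be in (0, 24]")
  }
  structure(list(valid_day_threshold_h = valid_day_threshold_h, tz = tz),
            class = "summary_config")
}

#' Summarize per-minute records into daily summaries
#'
#' Each calendar day (local midnight boundary) with at least one covered
#' minute yields one summary row. Wear time is the total covered (classified)
#' time -- non-wear is absent data by the pipeline's convention -- and the
#' active minutes are the day's standing plus dynamic (walking) seconds
#' divided by 60. The postoperative-day index counts calendar days since
#' surgery, surgery day being POD 0 so POD 1 is the first full day after the
#' operation.
#'
#' @param minutes Per-minute records (see \code{\link{aggregate_minutes}}).
#' @param surgery_date Date of surgery.
#' @param config A \code{\link{summary_config}}.
#' @param patient_id Optional patient identifier carried into the output.
#' @return A data.frame with columns \code{patient_id}, \code{date},
#'   \code{pod}, \code{wear_h}, \code{valid}, \code{active_min},
#'   \code{sedentary_min}.
#' @export
summarize_days <- function(minutes, surgery_date, config = summary_config(),
                           patient_id = NA_character_) {
  assert_columns(minutes,
                 c("minute_start", "sedentary_s", "standing_s", "dynamic_s",
                   "covered_s"), "minutes")
  if (!nrow(minutes)) {
    stop_input("input error: no minute records to summarize")
  }
  surgery_date <- as.Date(surgery_date)
  date <- as.Date(epoch_to_posix(as_epoch(minutes$minute_start), config$tz),
                  tz = config$tz)
  if (surgery_date > max(date)) {
    stop_input("indexing error: surgery_date is after all recorded data")
  }
  udate <- sort(unique(date))
  idx <- match(date, udate)
  sum_by <- function(x) rowsum(as.numeric(x), idx)[, 1L]
  covered <- sum_by(minutes$covered_s)
  active <- sum_by(minutes$standing_s + minutes$dynamic_s)
  sedentary <- sum_by(minutes$sedentary_s)
  out <- data.frame(
    patient_id = patient_id,
    date = udate,
    pod = as.integer(udate - surgery_date),
    wear_h = covered / 3600,
    active_min = active / 60,
    sedentary_min = sedentary / 60,
    stringsAsFactors = FALSE)
  out$valid <- out$wear_h >= config$valid_day_threshold_h
  out[, c("patient_id", "date", "pod", "wear_h", "valid",
          "active_min", "sedentary_min")]
}

#' Select per-patient active minutes on one postoperative day
#'
#' Returns, for every patient present in the summaries, the active minutes
#' of their valid measurement day at the requested POD. Patients with no
#' valid day at that POD get \code{NA} (missing), never zero: an invalid or
#' absent day is a measurement failure, not an inactive day.
#'
#' @param summaries Daily summaries (rows from \code{\link{summarize_days}},
#'   possibly many patients).
#' @param pod Postoperative day index to analyze (default 1).
#' @return A data.frame \code{patient_id}, \code{active_min} with one row
#'   per patient in \code{summaries}.
#' @export
select_analysis_days <- function(summaries, pod = 1) {
  assert_columns(summaries, c("patient_id", "pod", "valid", "active_min"),
                 "summaries")
  if (pod < 0) stop_input("pod must be >= 0")
  ids <- unique(summaries$patient_id)
  hit <- summaries[summaries$pod == pod & summaries$valid, , drop = FALSE]
  # one valid day per patient per POD by construction; keep the first defensively
  hit <- hit[!duplicated(hit$patient_id), , drop = FALSE]
  data.frame(patient_id = ids,
             active_min = hit$active_min[match(ids, hit$patient_id)],
             stringsAsFactors = FALSE)
}
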