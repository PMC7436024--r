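# Modified Iowa Level of Assistance Scale (mILAS) scoring and the
# dichotomized functional-recovery-on-POD1 endpoint.
#
# Five activities of daily living are scored 0-6 by the physiotherapist
# (0 = fully independent, 6 = maximal assistance): supine-to-sit transfer,
# sit-to-supine transfer, sit-to-stand, walking, and stair climbing. The
# total ranges 0-30; stair climbing is only assessed when the patient has
# stairs at home, otherwise it scores 0.

MILAS_ITEMS <- c("supine_to_sit", "sit_to_supine", "sit_to_stand",
                 "walking", "stairs")

validate_milas_items <- function(items) {
  for (it in MILAS_ITEMS) {
    v <- items[[it]]
    if (any(!is.na(v) & (v < 0 | v > 6 | v != round(v)))) {
      stop_input("validation error: mILAS item `", it,
                 "` must be an integer in 0-6")
    }
  }
  invisible(items)
}

#' Total mILAS score
#'
#' Sums the five item scores after applying the stairs rule: when the
#' patient does not need to climb stairs at home the stair item counts as 0
#' regardless of any recorded value.
#'
#' @param assessment A data.frame (or list) with columns
#'   \code{supine_to_sit}, \code{sit_to_supine}, \code{sit_to_stand},
#'   \code{walking}, \code{stairs} (each 0-6) and logical
#'   \code{needs_stairs_at_home}.
#' @return Integer total score(s), 0-30 (0 = full independence).
#' @export
milas_total <- function(assessment) {
  assert_columns(as.data.frame(assessment),
                 c(MILAS_ITEMS, "needs_stairs_at_home"), "assessment")
  validate_milas_items(assessment)
  stairs <- ifelse(assessment$needs_stairs_at_home, assessment$stairs, 0L)
  as.integer(assessment$supine_to_sit + assessment$sit_to_supine +
               assessment$sit_to_stand + assessment$walking + stairs)
}

#' Percentage transformation of mILAS scores
#'
#' The app-style percentage view: 100% is complete independence. The overall
#' percentage is the linear complement of the total, (30 - total)/30 x 100;
#' each activity's percentage is (6 - item)/6 x 100 after the stairs rule.
#'
#' @inheritParams milas_total
#' @return A data.frame with \code{overall_pct} and one \code{<item>_pct}
#'   column per activity.
#' @export
milas_percentage <- function(assessment) {
  assessment <- as.data.frame(assessment)
  total <- milas_total(assessment)
  out <- data.frame(overall_pct = (30 - total) / 30 * 100)
  stairs <- ifelse(assessment$needs_stairs_at_home, assessment$stairs, 0L)
  items <- assessment[MILAS_ITEMS]
  items$stairs <- stairs
  for (it in MILAS_ITEMS) {
    out[[paste0(it, "_pct")]] <- (6 - items[[it]]) / 6 * 100
  }
  out
}

#' Dichotomized functional recovery on POD1
#'
#' Functional recovery is reached when the total mILAS score first hits 0.
#' A patient may be assessed multiple times per day; the day's minimum total
#' governs, since recovery is a ratchet in clinical use. The endpoint is
#' coded 1 when the first zero-total day is on or before POD1 and 0
#' otherwise (including patients who never reach zero during monitoring).
#'
#' @param assessments Data.frame with \code{patient_id}, \code{timestamp}
#'   (POSIXct), the five item columns and \code{needs_stairs_at_home}.
#' @param surgery_dates Either a single surgery date (recycled) or a
#'   data.frame \code{patient_id, surgery_date}.
#' @param tz Timezone for the calendar-day boundary.
#' @return A data.frame \code{patient_id}, \code{first_zero_pod} (integer,
#'   \code{NA} if never zero), \code{recovered_on_pod1} (0/1).
#' @export
recovery_endpoint <- function(assessments, surgery_dates, tz = "UTC") {
  assert_columns(assessments, c("patient_id", "timestamp"), "assessments")
  if (!nrow(assessments)) stop_input("input error: no assessments")
  total <- milas_total(assessments)
  if (is.data.frame(surgery_dates)) {
    assert_columns(surgery_dates, c("patient_id", "surgery_date"),
                   "surgery_dates")
    sdate <- as.Date(surgery_dates$surgery_date)[
      match(assessments$patient_id, surgery_dates$patient_id)]
    if (anyNA(sdate)) {
      stop_input("input error: assessments for patients without a surgery date")
    }
  } else {
    sdate <- as.Date(surgery_dates)
  }
  day <- as.Date(epoch_to_posix(as_epoch(assessments$timestamp), tz), tz = tz)
  pod <- as.integer(day - sdate)

  per <- split(data.frame(pod = pod, total = total),
               assessments$patient_id)
  first_zero <- vapply(per, function(d) {
    day_min <- tapply(d$total, d$pod, min)
    zeros <- as.integer(names(day_min))[day_min == 0]
    if (length(zeros)) min(zeros) else NA_integer_
  }, integer(1))
  data.frame(patient_id = names(per),
             first_zero_pod = unname(first_zero),
             recovered_on_pod1 = as.integer(!is.na(first_zero) & first_zero <= 1),
             stringsAsFactors = FALSE)
}
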