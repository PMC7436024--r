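# Posture-bout schedules and sensor configuration for the signal simulator.

POSTURES <- c("lying", "sitting", "standing", "walking", "nonwear")

#' Sensor configuration for the signal simulator
#'
#' Describes the thigh-worn tri-axial accelerometer being emulated: a 25 Hz
#' sampler with a +/- 8 g range and Gaussian sensor noise. The longitudinal
#' axis is the sensor axis aligned with the femur, which carries the gravity
#' component when the patient is upright; the mounting orientation is
#' configurable because it depends on how the device is fixed to the thigh.
#'
#' Walking is emulated as a sinusoidal oscillation of the longitudinal axis
#' around the upright orientation. The defaults (1.5 Hz step frequency,
#' 0.4 g amplitude) describe the slow, aided gait of patients in the first
#' days after arthroplasty; they are deliberately simple -- just enough
#' signal structure for the dynamic/static split to operate on -- and make no
#' claim to biomechanical realism.
#'
#' @param sample_rate_hz Nominal sampling rate in Hz (device default 25).
#' @param range_g Sensor range; generated samples are clipped to
#'   \code{[-range_g, range_g]}.
#' @param noise_sd_g Standard deviation of additive Gaussian noise per axis,
#'   in g. The default 0.05 g summarizes sensor jitter plus small postural
#'   tremor; set to 0 for noiseless oracle signals.
#' @param longitudinal_axis Which sensor axis lies along the thigh:
#'   \code{"x"}, \code{"y"} or \code{"z"} (default \code{"z"}).
#' @param gait_freq_hz Step frequency used for walking bouts, Hz.
#' @param gait_amp_g Amplitude of the walking oscillation, g.
#' @return A list of class \code{sensor_config}.
#' @export
sensor_config <- function(sample_rate_hz = 25, range_g = 8, noise_sd_g = 0.05,
                          longitudinal_axis = "z", gait_freq_hz = 1.5,
                          gait_amp_g = 0.4) {
  assert_positive(sample_rate_hz, "sample_rate_hz")
  assert_positive(range_g, "range_g")
  assert_positive(noise_sd_g, "noise_sd_g", strict = FALSE)
  assert_positive(gait_freq_hz, "gait_freq_hz")
  assert_positive(gait_amp_g, "gait_amp_g", strict = FALSE)
  longitudinal_axis <- match.arg(tolower(longitudinal_axis), c("x", "y", "z"))
  structure(list(sample_rate_hz = sample_rate_hz, range_g = range_g,
                 noise_sd_g = noise_sd_g, longitudinal_axis = longitudinal_axis,
                 gait_freq_hz = gait_freq_hz, gait_amp_g = gait_amp_g),
            class = "sensor_config")
}

#' Build and validate a posture-bout schedule
#'
#' A schedule is the ground truth a simulated signal is generated from: an
#' ordered sequence of non-overlapping bouts, each with a start time, a
#' duration in seconds and a posture label among lying, sitting, standing,
#' walking and nonwear. Nonwear bouts produce no samples (the device
#' transmits nothing when not worn).
#'
#' @param start_time POSIXct (or epoch seconds) start of each bout.
#' @param duration_s Bout durations in seconds, each >= 1.
#' @param posture Character vector of posture labels.
#' @param tz Timezone used when start_time is numeric.
#' @return A data.frame of class \code{posture_schedule} with columns
#'   \code{start_time}, \code{duration_s}, \code{posture}.
#' @export
posture_schedule <- function(start_time, duration_s, posture, tz = "UTC") {
  if (length(start_time) != length(duration_s) ||
      length(start_time) != length(posture)) {
    stop_input("start_time, duration_s and posture must have equal length")
  }
  posture <- as.character(posture)
  bad <- setdiff(unique(posture), POSTURES)
  if (length(bad)) {
    stop_input("unknown posture label(s): ", paste(bad, collapse = ", "))
  }
  if (any(!is.finite(duration_s)) || any(duration_s < 1)) {
    stop_input("every bout must have duration_s >= 1")
  }
  start <- as_epoch(start_time)
  ord <- order(start)
  start <- start[ord]; duration_s <- duration_s[ord]; posture <- posture[ord]
  if (length(start) > 1L) {
    ends <- start[-length(start)] + duration_s[-length(duration_s)]
    if (any(start[-1L] < ends - 1e-9)) {
      stop_input("schedule error: bouts overlap")
    }
  }
  out <- data.frame(start_time = epoch_to_posix(start, tz),
                    duration_s = as.numeric(duration_s),
                    posture = posture, stringsAsFactors = FALSE)
  class(out) <- c("posture_schedule", "data.frame")
  out
}

#' Simulate one ward day's posture schedule
#'
#' Generates a daily bout schedule with the structure observed on an
#' orthopedic ward: patients spend the vast majority of the day (>= 92%)
#' lying or sitting, interrupted by short standing bouts (transfers, standing
#' at the bed) and brief, slow walking bouts. Standing and walking minutes
#' are drawn to hit a per-day activity target, so downstream recovery of
#' "minutes standing and walking" can be checked against the schedule itself.
#'
#' @param day_start POSIXct start of the covered period (device fixation).
#' @param wear_s Seconds of wear to schedule (default a full 24 h day).
#' @param active_min Target minutes of standing + walking for the day.
#' @param walk_fraction Fraction of active time spent walking (vs standing).
#' @param mean_active_bout_s Mean duration of one standing/walking bout.
#' @param seed Integer seed; same seed, same schedule.
#' @param tz Timezone for bout timestamps.
#' @return A \code{\link{posture_schedule}}.
#' @export
simulate_schedule <- function(day_start, wear_s = 86400, active_min = 80,
                              walk_fraction = 0.4, mean_active_bout_s = 120,
                              seed = NULL, tz = "UTC") {
  if (!is.null(seed)) set.seed(seed)
  assert_positive(wear_s, "wear_s")
  assert_positive(mean_active_bout_s, "mean_active_bout_s")
  active_s <- min(active_min * 60, 0.9 * wear_s)
  start <- floor(as_epoch(day_start))

  # carve active time into bouts of ~mean_active_bout_s seconds
  n_active <- max(1L, round(active_s / mean_active_bout_s))
  w <- runif(n_active, 0.5, 1.5)
  bout_s <- pmax(10, round(active_s * w / sum(w)))
  is_walk <- runif(n_active) < walk_fraction
  active_post <- ifelse(is_walk, "walking", "standing")

  # interleave with long lying/sitting rest bouts
  rest_s_total <- wear_s - sum(bout_s)
  n_rest <- n_active + 1L
  wr <- runif(n_rest, 0.4, 1.6)
  rest_s <- pmax(60, round(rest_s_total * wr / sum(wr)))
  rest_post <- sample(c("lying", "sitting"), n_rest, replace = TRUE,
                      prob = c(0.6, 0.4))

  dur <- numeric(0); post <- character(0)
  for (i in seq_len(n_active)) {
    dur <- c(dur, rest_s[i], bout_s[i])
    post <- c(post, rest_post[i], active_post[i])
  }
  dur <- c(dur, rest_s[n_rest]); post <- c(post, rest_post[n_rest])

  # trim/extend the last rest bout so the schedule covers exactly wear_s
  excess <- sum(dur) - wear_s
  dur[length(dur)] <- max(60, dur[length(dur)] - excess)
  starts <- start + cumsum(c(0, dur[-length(dur)]))
  posture_schedule(starts, dur, post, tz = tz)
}

# Seconds of each posture per calendar day implied by a schedule; the oracle
# used by end-to-end tests.
schedule_posture_seconds <- function(schedule, tz = "UTC") {
  sec_start <- floor(as_epoch(schedule$start_time))
  rows <- lapply(seq_len(nrow(schedule)), function(i) {
    secs <- seq(sec_start[i], length.out = schedule$duration_s[i], by = 1)
    data.frame(sec = secs, posture = schedule$posture[i],
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, rows)
  all$date <- as.Date(epoch_to_posix(all$sec, tz))
  agg <- as.data.frame(table(all$date, all$posture), stringsAsFactors = FALSE)
  names(agg) <- c("date", "posture", "seconds")
  agg$date <- as.Date(agg$date)
  agg[agg$seconds > 0, , drop = FALSE]
}
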