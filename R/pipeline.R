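# Embedded posture-classification pipeline: noise reduction, fixed 1-s
# windowing, dynamic/static split, 0.8 g standing/sedentary rule, per-minute
# aggregation.

#' Classifier configuration
#'
#' Parameters of the window classifier. The 0.8 g orientation cut-off is the
#' published decision boundary between standing and sedentary static windows;
#' the remaining parameters (activity-dispersion threshold, low-pass cut-off,
#' minimum samples per window) are documented implementation choices and are
#' exposed here so they can be stressed in tests.
#'
#' @param dynamic_threshold_g Dispersion cut-off (g) above which a 1-s window
#'   is dynamic. The dispersion statistic is the mean Euclidean deviation of
#'   the acceleration vector from its window mean, which responds both to
#'   magnitude changes and to pure re-orientations; default 0.1 g.
#' @param orientation_cutoff_g Static windows with mean absolute longitudinal
#'   acceleration at or above this value are standing, below it sedentary.
#'   Default exactly 0.8; the boundary is inclusive (0.8 g => standing).
#' @param longitudinal_axis Sensor axis aligned with the thigh (default "z").
#'   The comparison is sign-insensitive because the mounting polarity is
#'   arbitrary.
#' @param noise_cutoff_hz Low-pass corner frequency of the noise-reduction
#'   filter (default 5 Hz: keeps gravity and the gait band, removes jitter).
#' @param min_window_samples Minimum samples for a 1-s window to be
#'   classified; sparser windows count as non-wear. Default 20 of 25.
#' @return A list of class \code{classifier_config}.
#' @export
classifier_config <- function(dynamic_threshold_g = 0.1,
                              orientation_cutoff_g = 0.8,
                              longitudinal_axis = "z",
                              noise_cutoff_hz = 5,
                              min_window_samples = 20) {
  assert_positive(dynamic_threshold_g, "dynamic_threshold_g")
  assert_positive(orientation_cutoff_g, "orientation_cutoff_g")
  assert_positive(noise_cutoff_hz, "noise_cutoff_hz")
  assert_positive(min_window_samples, "min_window_samples")
  longitudinal_axis <- match.arg(tolower(longitudinal_axis), c("x", "y", "z"))
  structure(list(dynamic_threshold_g = dynamic_threshold_g,
                 orientation_cutoff_g = orientation_cutoff_g,
                 longitudinal_axis = longitudinal_axis,
                 noise_cutoff_hz = noise_cutoff_hz,
                 min_window_samples = min_window_samples),
            class = "classifier_config")
}

# Zero-phase low-pass of one numeric vector. signal::filtfilt alone has edge
# transients, so the series is mean-removed and odd-reflection padded first;
# a constant segment therefore passes through exactly.
lowpass_zerophase <- function(x, rate, cutoff_hz, order = 4) {
  n <- length(x)
  if (n < 3 * (order + 1)) return(x) # too short to filter meaningfully
  if (cutoff_hz >= rate / 2) return(x)
  bf <- signal::butter(order, cutoff_hz / (rate / 2), type = "low")
  m <- mean(x)
  xc <- x - m
  pad <- min(n - 1L, as.integer(3 * rate))
  left <- 2 * xc[1L] - xc[seq(pad + 1L, 2L)]
  right <- 2 * xc[n] - xc[seq(n - 1L, n - pad)]
  y <- signal::filtfilt(bf, c(left, xc, right))
  y[seq(pad + 1L, pad + n)] + m
}

# Split sample indices into contiguous runs (gap > 1.5 sample intervals
# starts a new run) so filtering never bridges non-wear gaps.
contiguous_runs <- function(times, rate) {
  if (!length(times)) return(integer(0))
  gaps <- c(FALSE, diff(times) > 1.5 / rate)
  cumsum(gaps)
}

#' Reduce sensor noise in a raw signal
#'
#' Applies a 4th-order Butterworth low-pass filter forward and backward
#' (zero phase) to each axis, independently within each contiguous stretch
#' of samples, so non-wear gaps are never bridged. Sample count and
#' timestamps are unchanged; a constant signal passes through exactly.
#'
#' @param signal A \code{raw_signal} data.frame (\code{time, x_g, y_g, z_g}).
#' @param config A \code{\link{classifier_config}}.
#' @return The filtered signal, same shape and class.
#' @export
denoise_signal <- function(signal, config = classifier_config()) {
  assert_columns(signal, c("time", "x_g", "y_g", "z_g"), "signal")
  if (!nrow(signal)) stop_input("input error: empty signal")
  rate <- attr(signal, "sample_rate_hz") %||% 25
  tt <- as_epoch(signal$time)
  run <- contiguous_runs(tt, rate)
  out <- signal
  for (ax in c("x_g", "y_g", "z_g")) {
    out[[ax]] <- unlist(lapply(split(signal[[ax]], run), lowpass_zerophase,
                               rate = rate, cutoff_hz = config$noise_cutoff_hz),
                        use.names = FALSE)
  }
  attr(out, "sample_rate_hz") <- rate
  out
}

#' Segment a signal into fixed non-overlapping 1-second windows
#'
#' Windows are anchored to whole epoch seconds. Each second of coverage that
#' contains at least \code{min_window_samples} samples yields one window with
#' its per-axis mean accelerations and the activity dispersion statistic
#' (mean Euclidean deviation of the sample vectors from the window mean).
#' Partial leading/trailing seconds and gap seconds yield no window.
#'
#' @param signal A \code{raw_signal} data.frame.
#' @param config A \code{\link{classifier_config}}.
#' @return A data.frame with one row per window: \code{second} (POSIXct
#'   window start), \code{n_samples}, \code{mean_x_g}, \code{mean_y_g},
#'   \code{mean_z_g}, \code{dispersion_g}.
#' @export
segment_windows <- function(signal, config = classifier_config()) {
  assert_columns(signal, c("time", "x_g", "y_g", "z_g"), "signal")
  tz <- if (inherits(signal$time, "POSIXct"))
    attr(signal$time, "tzone") %||% "UTC" else "UTC"
  if (!nrow(signal)) {
    return(data.frame(second = epoch_to_posix(numeric(0), tz),
                      n_samples = integer(0), mean_x_g = numeric(0),
                      mean_y_g = numeric(0), mean_z_g = numeric(0),
                      dispersion_g = numeric(0)))
  }
  tt <- as_epoch(signal$time)
  if (is.unsorted(tt, strictly = TRUE)) {
    stop_input("input error: timestamps must be strictly increasing")
  }
  sec <- floor(tt)
  usec <- sort(unique(sec))
  f <- match(sec, usec) # integer group ids in time order
  n <- tabulate(f, nbins = length(usec))
  mx <- rowsum(signal$x_g, f) / n
  my <- rowsum(signal$y_g, f) / n
  mz <- rowsum(signal$z_g, f) / n
  # activity dispersion: mean Euclidean deviation of each sample from the
  # window-mean acceleration vector. Sensitive both to magnitude changes and
  # to pure orientation changes (which keep |a| constant).
  dev <- sqrt((signal$x_g - mx[f])^2 + (signal$y_g - my[f])^2 +
                (signal$z_g - mz[f])^2)
  disp <- rowsum(dev, f) / n

  keep <- n >= config$min_window_samples
  out <- data.frame(
    second = epoch_to_posix(usec, tz)[keep],
    n_samples = n[keep],
    mean_x_g = mx[keep, 1L], mean_y_g = my[keep, 1L], mean_z_g = mz[keep, 1L],
    dispersion_g = disp[keep, 1L])
  rownames(out) <- NULL
  out
}

#' Classify 1-second windows as dynamic, standing or sedentary
#'
#' A window whose activity dispersion exceeds the dynamic threshold is
#' \code{dynamic} (ambulation). Otherwise the static window's orientation is
#' assessed: mean absolute acceleration along the longitudinal (thigh) axis
#' at or above the 0.8 g cut-off means the thigh is near vertical, so the
#' window is \code{standing}; below it the patient is \code{sedentary}
#' (lying or sitting).
#'
#' @param windows Output of \code{\link{segment_windows}}.
#' @param config A \code{\link{classifier_config}}.
#' @return \code{windows} with an added factor column \code{label} with
#'   levels \code{dynamic}, \code{standing}, \code{sedentary}.
#' @export
classify_windows <- function(windows, config = classifier_config()) {
  assert_columns(windows, c("second", "dispersion_g"), "windows")
  ax_col <- paste0("mean_", config$longitudinal_axis, "_g")
  if (!ax_col %in% names(windows)) {
    stop_input("config error: longitudinal axis column ", ax_col,
               " not present in windows")
  }
  long_mean <- abs(windows[[ax_col]])
  label <- ifelse(windows$dispersion_g > config$dynamic_threshold_g, "dynamic",
                  ifelse(long_mean >= config$orientation_cutoff_g,
                         "standing", "sedentary"))
  windows$label <- factor(label, levels = c("dynamic", "standing", "sedentary"))
  windows
}

#' Aggregate classified windows into per-minute records
#'
#' Emulates the device's once-a-minute transmission: every wall-clock minute
#' containing at least one classified window becomes a record counting its
#' sedentary, standing and dynamic seconds. The three counts always
#' partition the covered seconds; minutes with data gaps simply have
#' \code{covered_s < 60}.
#'
#' @param windows Output of \code{\link{classify_windows}}.
#' @return A data.frame with one row per minute: \code{minute_start}
#'   (POSIXct), \code{sedentary_s}, \code{standing_s}, \code{dynamic_s},
#'   \code{covered_s}.
#' @export
aggregate_minutes <- function(windows) {
  assert_columns(windows, c("second", "label"), "windows")
  tz <- attr(windows$second, "tzone") %||% "UTC"
  if (!nrow(windows)) {
    return(data.frame(minute_start = epoch_to_posix(numeric(0), tz),
                      sedentary_s = integer(0), standing_s = integer(0),
                      dynamic_s = integer(0), covered_s = integer(0)))
  }
  minute <- floor(as_epoch(windows$second) / 60) * 60
  umin <- sort(unique(minute))
  idx <- match(minute, umin)
  count_label <- function(lab) {
    tabulate(idx[windows$label == lab], nbins = length(umin))
  }
  out <- data.frame(
    minute_start = epoch_to_posix(umin, tz),
    sedentary_s = count_label("sedentary"),
    standing_s = count_label("standing"),
    dynamic_s = count_label("dynamic"))
  out$covered_s <- out$sedentary_s + out$standing_s + out$dynamic_s
  rownames(out) <- NULL
  out
}

#' Run the full classification chain on a raw signal
#'
#' Convenience wrapper: \code{\link{denoise_signal}} then
#' \code{\link{segment_windows}}, \code{\link{classify_windows}} and
#' \code{\link{aggregate_minutes}}.
#'
#' @param signal A \code{raw_signal} data.frame.
#' @param config A \code{\link{classifier_config}}.
#' @return Per-minute records (see \code{\link{aggregate_minutes}}).
#' @export
classify_signal <- function(signal, config = classifier_config()) {
  aggregate_minutes(classify_windows(
    segment_windows(denoise_signal(signal, config), config), config))
}
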