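# Seeded tri-axial signal simulator: schedule -> raw accelerometer trace.

#' Simulate a raw tri-axial accelerometer signal from a posture schedule
#'
#' Produces one sample every \code{1/sample_rate_hz} seconds within each
#' covered bout, in g units, mimicking a thigh-worn sensor:
#' \itemize{
#'   \item \strong{standing}: gravity (1 g) on the longitudinal (thigh)
#'     axis -- the thigh is vertical;
#'   \item \strong{walking}: the standing orientation plus a sinusoidal
#'     oscillation of the longitudinal axis at the configured step frequency
#'     and amplitude;
#'   \item \strong{lying}: the thigh horizontal, gravity entirely on the
#'     first transverse axis, longitudinal component 0 g;
#'   \item \strong{sitting}: thigh nearly horizontal with a slight (20 degree)
#'     upward tilt, so the longitudinal component is about 0.34 g -- well
#'     below the 0.8 g standing cut-off;
#'   \item \strong{nonwear}: no samples at all (the device transmits
#'     nothing when it is not fixed to the patient).
#' }
#' Independent Gaussian noise of sd \code{noise_sd_g} is added per axis and
#' samples are clipped to the sensor range.
#'
#' @param schedule A \code{\link{posture_schedule}} (non-overlapping bouts).
#' @param config A \code{\link{sensor_config}}.
#' @param seed Integer seed; identical seed and schedule give a
#'   byte-identical signal.
#' @param tz Timezone for sample timestamps.
#' @return A data.frame of class \code{raw_signal} with columns \code{time}
#'   (POSIXct), \code{x_g}, \code{y_g}, \code{z_g}, and attribute
#'   \code{sample_rate_hz}.
#' @export
simulate_signal <- function(schedule, config = sensor_config(), seed = NULL,
                            tz = "UTC") {
  if (!inherits(schedule, "posture_schedule")) {
    schedule <- posture_schedule(schedule$start_time, schedule$duration_s,
                                 schedule$posture, tz = tz)
  }
  if (!inherits(config, "sensor_config")) stop_input("config error: need a sensor_config")
  if (!is.null(seed)) set.seed(seed)

  rate <- config$sample_rate_hz
  dt <- 1 / rate
  axes <- c("x", "y", "z")
  long <- config$longitudinal_axis
  trans <- setdiff(axes, long) # trans[1] carries gravity when horizontal

  worn <- schedule[schedule$posture != "nonwear", , drop = FALSE]
  if (!nrow(worn)) {
    out <- data.frame(time = epoch_to_posix(numeric(0), tz),
                      x_g = numeric(0), y_g = numeric(0), z_g = numeric(0))
    attr(out, "sample_rate_hz") <- rate
    class(out) <- c("raw_signal", "data.frame")
    return(out)
  }

  pieces <- lapply(seq_len(nrow(worn)), function(i) {
    n <- round(worn$duration_s[i] * rate)
    tt <- as_epoch(worn$start_time[i]) + (seq_len(n) - 1L) * dt
    base <- matrix(0, nrow = n, ncol = 3,
                   dimnames = list(NULL, axes))
    p <- worn$posture[i]
    if (p == "standing") {
      base[, long] <- 1
    } else if (p == "walking") {
      phase <- 2 * pi * config$gait_freq_hz * (tt - tt[1L])
      base[, long] <- 1 + config$gait_amp_g * sin(phase)
      base[, trans[1L]] <- 0.25 * config$gait_amp_g * sin(phase + pi / 3)
    } else if (p == "lying") {
      base[, trans[1L]] <- 1
    } else if (p == "sitting") {
      tilt <- 20 * pi / 180
      base[, long] <- sin(tilt)
      base[, trans[1L]] <- cos(tilt)
    }
    list(t = tt, a = base)
  })

  tt <- do.call(c, lapply(pieces, `[[`, "t"))
  acc <- do.call(rbind, lapply(pieces, `[[`, "a"))
  if (config$noise_sd_g > 0) {
    acc <- acc + matrix(rnorm(length(acc), sd = config$noise_sd_g),
                        nrow = nrow(acc))
  }
  acc <- pmin(pmax(acc, -config$range_g), config$range_g)

  out <- data.frame(time = epoch_to_posix(tt, tz),
                    x_g = acc[, "x"], y_g = acc[, "y"], z_g = acc[, "z"])
  attr(out, "sample_rate_hz") <- rate
  class(out) <- c("raw_signal", "data.frame")
  out
}
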