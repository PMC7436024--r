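# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# All wall-clock arithmetic in the package flows through one timezone so that
# seeded fixtures are identical across machines.
aw_tz <- function(tz = NULL) tz %||% "UTC"

as_epoch <- function(time) {
  if (inherits(time, "POSIXct")) as.numeric(time) else as.numeric(time)
}

epoch_to_posix <- function(x, tz = "UTC") as.POSIXct(x, origin = "1970-01-01", tz = tz)

stop_input <- function(...) stop(..., call. = FALSE)

# sample() treats a length-1 numeric x as 1:x; this never does.
resample <- function(x, size) x[sample.int(length(x), size)]

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_input(sprintf("%s is missing required column(s): %s",
                       what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop_input(sprintf("`%s` must be TRUE or FALSE", name))
  }
  invisible(x)
}

assert_positive <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok) {
    stop_input(sprintf("`%s` must be a %s number", name,
                       if (strict) "positive" else "non-negative"))
  }
  invisible(x)
}
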