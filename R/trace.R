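#' Construct a uniformly sampled chest-acceleration trace
#'
#' The basic container for a single-axis seismocardiogram: a numeric sample
#' vector plus its sampling rate. Acceleration units are deliberately left
#' unspecified ("accel units"); every downstream statistic is either
#' unit-agnostic (rates, the healthy measure) or expressed in rate units.
#'
#' @param samples numeric vector of acceleration values; must be finite.
#' @param sampling_rate_hz sampling rate in Hz, > 0.
#' @param start_time_s time of the first sample in seconds (default 0).
#' @return An object of class `acceleration_trace`: a list with elements
#'   `samples`, `sampling_rate_hz`, `start_time_s`.
#' @examples
#' tr <- acceleration_trace(sin(2 * pi * 0.3 * (0:499) / 50), 50)
#' tr
#' @export
acceleration_trace <- function(samples, sampling_rate_hz, start_time_s = 0) {
  if (!is.numeric(samples)) {
    stop_invalid_trace("'samples' must be numeric")
  }
  if (!is_scalar_number(sampling_rate_hz) || sampling_rate_hz <= 0) {
    stop_invalid_trace("'sampling_rate_hz' must be a single positive number")
  }
  if (anyNA(samples) || any(!is.finite(samples))) {
    stop_invalid_trace("trace contains NaN/Inf/NA samples")
  }
  structure(
    list(
      samples = as.numeric(samples),
      sampling_rate_hz = as.numeric(sampling_rate_hz),
      start_time_s = as.numeric(start_time_s)
    ),
    class = "acceleration_trace"
  )
}

#' @export
print.acceleration_trace <- function(x, ...) {
  cat(sprintf(
    "<acceleration_trace> %d samples @ %g Hz (%.1f s, start %.2f s)\n",
    length(x$samples), x$sampling_rate_hz,
    length(x$samples) / x$sampling_rate_hz, x$start_time_s
  ))
  invisible(x)
}

#' @export
length.acceleration_trace <- function(x) length(x$samples)

#' Sample times of a trace
#'
#' @param trace an `acceleration_trace`.
#' @return numeric vector of sample times in seconds.
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "acceleration_trace"))
  trace$start_time_s +
    (seq_along(trace$samples) - 1L) / trace$sampling_rate_hz
}

#' @export
as.data.frame.acceleration_trace <- function(x, ...) {
  data.frame(time_s = trace_times(x), accel = x$samples)
}

#' Read a chest-acceleration trace from CSV
#'
#' Expects a header `time_s,accel`, a strictly increasing time column and
#' uniform sampling: every inter-sample interval must be within 1% of the
#' median period, otherwise the offending data line is reported. The sampling
#' rate is inferred as the reciprocal of the median period.
#'
#' @param path path to a CSV file.
#' @return an [acceleration_trace()].
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) {
    stop_invalid_input(sprintf("trace file not found: '%s'", path))
  }
  df <- utils::read.csv(path)
  need <- c("time_s", "accel")
  if (!all(need %in% names(df))) {
    stop_invalid_input(sprintf(
      "trace CSV '%s' must have columns time_s,accel (found: %s)",
      path, paste(names(df), collapse = ",")
    ))
  }
  t <- df$time_s
  if (length(t) < 2L) {
    stop_insufficient_data("trace CSV has fewer than 2 rows")
  }
  d <- diff(t)
  bad <- which(d <= 0)
  if (length(bad)) {
    # +2: one for diff offset, one for the header line
    stop_invalid_input(sprintf(
      "non-monotone time at line %d of '%s' (time_s %g after %g)",
      bad[1L] + 2L, path, t[bad[1L] + 1L], t[bad[1L]]
    ))
  }
  period <- stats::median(d)
  irregular <- which(abs(d - period) > 0.01 * period)
  if (length(irregular)) {
    stop_invalid_input(sprintf(
      "irregular sampling at line %d of '%s' (interval %g s, expected %g s)",
      irregular[1L] + 2L, path, d[irregular[1L]], period
    ))
  }
  acceleration_trace(df$accel, sampling_rate_hz = 1 / period,
                     start_time_s = t[1L])
}

#' Write a trace to CSV (`time_s,accel`)
#'
#' Values are printed with 17 significant digits so a write/read round trip
#' reproduces the samples exactly.
#'
#' @param trace an `acceleration_trace`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "acceleration_trace"))
  df <- as.data.frame(trace)
  lines <- c("time_s,accel",
             sprintf("%.17g,%.17g", df$time_s, df$accel))
  writeLines(lines, path)
  invisible(path)
}
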