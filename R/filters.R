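#' Filter specification for cardiac/respiratory band separation
#'
#' The separation uses a pair of Butterworth filters sharing one physical
#' cutoff: a high-pass whose output is the cardiac component and a low-pass
#' whose output is the respiratory component. Defaults follow the wearable
#' acquisition design this package targets: order 2, cutoff 0.5 Hz at a 50 Hz
#' sampling rate.
#'
#' @param order filter order, positive integer (default 2).
#' @param cutoff_hz cutoff frequency in Hz (default 0.5). Used for both
#'   filters unless `cutoff_low_hz` is given for the low-pass.
#' @param cutoff_low_hz optional separate low-pass cutoff in Hz (defaults to
#'   `cutoff_hz`).
#' @param mode `"zero_phase_offline"` (forward-backward filtering, zero phase
#'   lag, squared magnitude response; the default, since peak timing matters
#'   downstream) or `"causal_streaming"` (single pass, group delay applies).
#' @return object of class `filter_spec`.
#' @export
filter_spec <- function(order = 2,
                        cutoff_hz = 0.5,
                        cutoff_low_hz = cutoff_hz,
                        mode = c("zero_phase_offline", "causal_streaming")) {
  mode <- match.arg(mode)
  if (!is_scalar_number(order) || order < 1 || order != round(order)) {
    stop_invalid_filter("'order' must be a positive integer")
  }
  if (!is_scalar_number(cutoff_hz) || cutoff_hz <= 0) {
    stop_invalid_filter("'cutoff_hz' must be a positive number")
  }
  if (!is_scalar_number(cutoff_low_hz) || cutoff_low_hz <= 0) {
    stop_invalid_filter("'cutoff_low_hz' must be a positive number")
  }
  structure(
    list(order = as.integer(order), cutoff_hz = cutoff_hz,
         cutoff_low_hz = cutoff_low_hz, mode = mode),
    class = "filter_spec"
  )
}

#' Normalized cutoff frequency
#'
#' Expresses a physical cutoff as a dimensionless fraction of a reference
#' frequency. Two conventions coexist in the signal-processing literature:
#' division by the sampling rate (0.5 Hz at 50 Hz gives 0.01) and division by
#' the Nyquist frequency (the same cutoff gives 0.02, the convention
#' `signal::butter` uses). Filters in this package are always designed from
#' the physical cutoff in Hz; this function only documents the conversion.
#'
#' @param cutoff_hz cutoff frequency in Hz.
#' @param sampling_rate_hz sampling rate in Hz.
#' @param convention `"sampling_rate"` or `"nyquist"`.
#' @return dimensionless fraction.
#' @examples
#' normalized_cutoff(0.5, 50, "sampling_rate") # 0.01
#' normalized_cutoff(0.5, 50, "nyquist") # 0.02
#' @export
normalized_cutoff <- function(cutoff_hz, sampling_rate_hz,
                              convention = c("sampling_rate", "nyquist")) {
  convention <- match.arg(convention)
  if (!is_scalar_number(cutoff_hz) || !is_scalar_number(sampling_rate_hz) ||
      cutoff_hz <= 0 || sampling_rate_hz <= 0) {
    stop_invalid_filter("cutoff and sampling rate must be positive numbers")
  }
  if (cutoff_hz >= sampling_rate_hz / 2) {
    stop_invalid_filter(sprintf(
      "cutoff %g Hz is at or above Nyquist (%g Hz)",
      cutoff_hz, sampling_rate_hz / 2
    ))
  }
  switch(convention,
    sampling_rate = cutoff_hz / sampling_rate_hz,
    nyquist = cutoff_hz / (sampling_rate_hz / 2)
  )
}

#' Design a digital Butterworth filter
#'
#' Thin wrapper over `signal::butter()` that validates the cutoff against
#' Nyquist and checks pole stability. The bilinear transform pre-warps at the
#' cutoff, so the -3 dB point sits exactly at `cutoff_hz`; away from the
#' cutoff the response follows the analog magnitude
#' 1/sqrt(1 + (f/fc)^(2n)) up to frequency warping, which is negligible while
#' the frequencies involved stay well below Nyquist.
#'
#' @param spec a [filter_spec()].
#' @param kind `"lowpass"` or `"highpass"`.
#' @param sampling_rate_hz sampling rate in Hz.
#' @return list with numeric coefficient vectors `b` (numerator), `a`
#'   (denominator) and the design metadata, class `butter_design`.
#' @export
design_butterworth <- function(spec, kind = c("lowpass", "highpass"),
                               sampling_rate_hz) {
  kind <- match.arg(kind)
  stopifnot(inherits(spec, "filter_spec"))
  fc <- if (kind == "lowpass") spec$cutoff_low_hz else spec$cutoff_hz
  if (fc >= sampling_rate_hz / 2) {
    stop_invalid_filter(sprintf(
      "cutoff %g Hz is at or above Nyquist (%g Hz)", fc, sampling_rate_hz / 2
    ))
  }
  ba <- signal::butter(spec$order, fc / (sampling_rate_hz / 2),
                       type = if (kind == "lowpass") "low" else "high")
  if (any(Mod(polyroot(rev(ba$a))) > 1 + 1e-8)) {
    stop("internal error: unstable Butterworth design (pole outside unit circle)")
  }
  structure(
    list(b = as.numeric(ba$b), a = as.numeric(ba$a), order = spec$order,
         cutoff_hz = fc, kind = kind, sampling_rate_hz = sampling_rate_hz),
    class = "butter_design"
  )
}

#' Magnitude response of a designed filter
#'
#' @param design a `butter_design`.
#' @param freq_hz frequencies in Hz at which to evaluate.
#' @return numeric vector of single-pass magnitudes.
#' @export
filter_magnitude <- function(design, freq_hz) {
  stopifnot(inherits(design, "butter_design"))
  z <- exp(-1i * 2 * pi * freq_hz / design$sampling_rate_hz)
  num <- vapply(z, function(zz) sum(design$b * zz^(seq_along(design$b) - 1L)),
                complex(1))
  den <- vapply(z, function(zz) sum(design$a * zz^(seq_along(design$a) - 1L)),
                complex(1))
  Mod(num / den)
}

apply_filter <- function(design, x, mode) {
  ba <- structure(list(b = design$b, a = design$a), class = "Arma")
  if (mode == "zero_phase_offline") {
    signal::filtfilt(ba, x)
  } else {
    as.numeric(signal::filter(ba, x))
  }
}

#' Separate a trace into cardiac and respiratory components
#'
#' Applies the high-pass filter to obtain the cardiac component and the
#' low-pass filter for the respiratory component. In the default
#' `zero_phase_offline` mode both filters run forward and backward, so peak
#' times are preserved (zero phase lag) and the effective magnitude response
#' is the square of the single-pass one. The first and last `transient_s`
#' seconds are flagged (not removed) so downstream windowing can exclude
#' filter settling.
#'
#' @param trace an [acceleration_trace()].
#' @param spec a [filter_spec()].
#' @param transient_s edge span flagged as transient, seconds (default 5; a
#'   second-order 0.5 Hz filter settles well within this).
#' @return object of class `band_separated`: list with `cardiac` and
#'   `respiratory` traces, the `filter_spec`, and `transient_s`.
#' @export
separate_bands <- function(trace, spec = filter_spec(), transient_s = 5) {
  if (!inherits(trace, "acceleration_trace")) {
    stop_invalid_trace("'trace' must be an acceleration_trace")
  }
  if (anyNA(trace$samples) || any(!is.finite(trace$samples))) {
    stop_invalid_trace("trace contains non-finite samples")
  }
  stopifnot(inherits(spec, "filter_spec"))
  if (length(trace$samples) < 10L * spec$order) {
    stop_insufficient_data(sprintf(
      "trace too short for filtering: %d samples, need at least %d",
      length(trace$samples), 10L * spec$order
    ))
  }
  fs <- trace$sampling_rate_hz
  hp <- design_butterworth(spec, "highpass", fs)
  lp <- design_butterworth(spec, "lowpass", fs)
  cardiac <- apply_filter(hp, trace$samples, spec$mode)
  respiratory <- apply_filter(lp, trace$samples, spec$mode)
  structure(
    list(
      cardiac = acceleration_trace(cardiac, fs, trace$start_time_s),
      respiratory = acceleration_trace(respiratory, fs, trace$start_time_s),
      filter_spec = spec,
      transient_s = transient_s
    ),
    class = "band_separated"
  )
}

#' @export
print.band_separated <- function(x, ...) {
  cat(sprintf(
    "<band_separated> %d samples @ %g Hz | order %d, high-pass %g Hz / low-pass %g Hz, %s\n",
    length(x$cardiac$samples), x$cardiac$sampling_rate_hz,
    x$filter_spec$order, x$filter_spec$cutoff_hz, x$filter_spec$cutoff_low_hz,
    x$filter_spec$mode
  ))
  invisible(x)
}
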