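#' Physiological validity bounds by signal kind
#'
#' Heartbeat estimates are considered physiologically valid in \[30, 220\]
#' beats/min and respiration in \[2, 60\] breaths/min; out-of-range windows
#' are carried with a validity flag, never dropped.
#'
#' @param kind `"heartbeat"` or `"respiration"`.
#' @return numeric length-2 vector (lower, upper) in events/min.
#' @export
rate_bounds <- function(kind = c("heartbeat", "respiration")) {
  kind <- match.arg(kind)
  if (kind == "heartbeat") c(30, 220) else c(2, 60)
}

default_refractory_s <- function(kind) {
  # refractory = period of the physiological rate ceiling
  if (kind == "heartbeat") 0.27 else 1.0
}

#' Detect peaks in a band-separated component
#'
#' Event detection is kind-specific because the two bands carry very
#' different waveforms.
#'
#' *Heartbeat*: each beat is a short high-frequency wavelet, so detection
#' runs on the RMS envelope of the cardiac band. The band is first detrended
#' with a short moving average (`detrend_s`, default 0.3 s) to remove the
#' residual respiratory leakage a second-order high-pass lets through near
#' its cutoff, then the envelope is the root of the moving mean of squares
#' over `envelope_s` (default 0.15 s). Strict local maxima of the envelope
#' exceeding `threshold_k` times its rolling standard deviation (centred
#' `rolling_window_s` window) are peak candidates; the envelope maximum of a
#' wavelet falls at the wavelet centre, so peak times track beat times.
#'
#' *Respiration*: the respiratory band is close to a slow sinusoid, whose
#' peak height is only ~1.4 rolling SDs — a threshold in units of the signal
#' SD would reject every breath. Candidates are strict local maxima of the
#' band itself, and the threshold is scaled by a rolling *noise* estimate:
#' the rolling SD of the residual after subtracting a `detrend_s` (1 s)
#' moving average, i.e. the part of the band too fast to be breathing. A
#' candidate is kept when it rises more than `threshold_k` noise SDs above
#' the rolling mean.
#'
#' In both cases ties break toward the earliest sample and a refractory pass
#' follows: of any two detections closer than `refractory_s`, the larger
#' survives. The refractory defaults encode rate ceilings of 220 beats/min
#' (0.27 s) and 60 breaths/min (1.0 s). A flat or empty component yields an
#' empty peak list, not an error.
#'
#' @param component an [acceleration_trace()] — the cardiac band output for
#'   heartbeat detection, the respiratory band for respiration.
#' @param kind `"heartbeat"` or `"respiration"`.
#' @param threshold_k threshold in rolling-SD units (default 1.5).
#' @param refractory_s minimum inter-peak spacing in seconds (default by
#'   `kind`).
#' @param rolling_window_s window for the rolling statistics (default 5 s).
#' @param detrend_s moving-average span for detrending, seconds (default
#'   0.3 for heartbeat, 1.0 for respiration).
#' @param envelope_s RMS envelope span for the cardiac band, seconds
#'   (default 0.15).
#' @param max_frac heartbeat only: a candidate must also exceed this
#'   fraction of the rolling envelope maximum (default 0.5), a scale-free
#'   gate against noise and leakage bumps between beats.
#' @return object of class `peak_list`: list with `peak_times_s`,
#'   `peak_amplitudes` (envelope height for heartbeat, band value for
#'   respiration), `detection_params`.
#' @export
detect_peaks <- function(component,
                         kind = c("heartbeat", "respiration"),
                         threshold_k = 1.5,
                         refractory_s = NULL,
                         rolling_window_s = 5,
                         detrend_s = NULL,
                         envelope_s = 0.15,
                         max_frac = 0.5) {
  kind <- match.arg(kind)
  if (!inherits(component, "acceleration_trace")) {
    stop_invalid_trace("'component' must be an acceleration_trace")
  }
  if (is.null(refractory_s)) refractory_s <- default_refractory_s(kind)
  if (is.null(detrend_s)) detrend_s <- if (kind == "heartbeat") 0.3 else 1.0
  fs <- component$sampling_rate_hz
  n <- length(component$samples)
  params <- list(kind = kind, threshold_k = threshold_k,
                 refractory_s = refractory_s,
                 rolling_window_s = rolling_window_s,
                 detrend_s = detrend_s,
                 envelope_s = if (kind == "heartbeat") envelope_s else NA)
  empty <- structure(
    list(peak_times_s = numeric(0), peak_amplitudes = numeric(0),
         detection_params = params),
    class = "peak_list"
  )
  if (n < 3L) return(empty)

  half_roll <- round(rolling_window_s * fs / 2)
  raw <- component$samples
  if (kind == "heartbeat") {
    trend <- rolling_moments(raw, round(detrend_s * fs / 2))$mean
    d <- raw - trend
    x <- sqrt(rolling_moments(d * d, round(envelope_s * fs / 2))$mean)
    # snap away cumulative-sum float noise so envelope plateaus are exact
    # ties and the earliest-sample rule applies deterministically
    x <- signif(x, 12L)
  } else {
    x <- raw
  }

  # strict rise, tie on the falling side -> earliest sample wins
  mid <- 2:(n - 1L)
  is_max <- x[mid] > x[mid - 1L] & x[mid] >= x[mid + 1L]
  cand <- mid[is_max]
  if (!length(cand)) return(empty)

  if (kind == "heartbeat") {
    roll_sd <- rolling_moments(x, half_roll)$sd
    roll_max <- rolling_max(x, half_roll)
    # the envelope peak of a beat dominates its 5 s neighbourhood; noise and
    # residual leakage bumps sit well below half the local maximum
    keep <- x[cand] > threshold_k * roll_sd[cand] &
      x[cand] > max_frac * roll_max[cand]
  } else {
    trend <- rolling_moments(raw, round(detrend_s * fs / 2))$mean
    noise_sd <- rolling_moments(raw - trend, half_roll)$sd
    roll_mean <- rolling_moments(raw, half_roll)$mean
    keep <- x[cand] - roll_mean[cand] > threshold_k * noise_sd[cand]
  }
  cand <- cand[keep]
  if (!length(cand)) return(empty)

  # refractory pass: the larger of two close detections survives
  min_gap <- refractory_s * fs
  out <- integer(length(cand))
  out[1L] <- cand[1L]
  m <- 1L
  for (i in cand[-1L]) {
    if (i - out[m] < min_gap) {
      if (x[i] > x[out[m]]) out[m] <- i
    } else {
      m <- m + 1L
      out[m] <- i
    }
  }
  out <- out[seq_len(m)]
  structure(
    list(
      peak_times_s = component$start_time_s + (out - 1L) / fs,
      peak_amplitudes = x[out],
      detection_params = params
    ),
    class = "peak_list"
  )
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("<peak_list> %d peaks (%s, k=%g, refractory %g s)\n",
              length(x$peak_times_s), x$detection_params$kind,
              x$detection_params$threshold_k,
              x$detection_params$refractory_s))
  invisible(x)
}

#' Windowed rate estimation from a peak train
#'
#' Slides a window of `window_length_s` by `hop_s` and, in each window,
#' estimates the rate as 60 / median(inter-peak intervals). The median is
#' preferred over peak counting because one missed peak doubles a single
#' interval but barely moves the median. Windows with fewer than 2 peaks,
#' with a rate outside the physiological bounds of `kind`, or overlapping a
#' flagged edge-transient span are carried with `valid = FALSE`.
#'
#' @param peaks a `peak_list` from [detect_peaks()].
#' @param window_length_s window length in seconds (default 60).
#' @param hop_s hop between window centres in seconds (default 10).
#' @param kind `"heartbeat"` or `"respiration"`; defaults to the kind the
#'   peaks were detected with.
#' @param duration_s recording duration used to lay out windows; defaults to
#'   the last peak time.
#' @param transient_s edge span whose overlapping windows are flagged invalid
#'   (default 0; the pipeline passes the band-separation transient).
#' @return object of class `rate_series`: a data.frame with columns
#'   `window_center_s`, `rate`, `n_peaks`, `valid`, plus attributes
#'   `window_length_s`, `hop_s`, `kind`.
#' @export
rate_from_peaks <- function(peaks, window_length_s = 60, hop_s = 10,
                            kind = NULL, duration_s = NULL,
                            transient_s = 0) {
  stopifnot(inherits(peaks, "peak_list"))
  if (!is_scalar_number(window_length_s) || window_length_s <= 0 ||
      !is_scalar_number(hop_s) || hop_s <= 0) {
    stop_invalid_config("window_length_s and hop_s must be positive")
  }
  if (is.null(kind)) kind <- peaks$detection_params$kind
  kind <- match.arg(kind, c("heartbeat", "respiration"))
  pt <- peaks$peak_times_s
  if (is.null(duration_s)) {
    duration_s <- if (length(pt)) max(pt) else window_length_s
  }
  half <- window_length_s / 2
  centers <- if (duration_s <= window_length_s) {
    duration_s / 2
  } else {
    seq(half, duration_s - half, by = hop_s)
  }
  bounds <- rate_bounds(kind)
  rate <- rep(NA_real_, length(centers))
  n_peaks <- integer(length(centers))
  valid <- logical(length(centers))
  for (j in seq_along(centers)) {
    inw <- pt >= centers[j] - half & pt <= centers[j] + half
    n_peaks[j] <- sum(inw)
    if (n_peaks[j] >= 2L) {
      r <- 60 / stats::median(diff(pt[inw]))
      rate[j] <- r
      valid[j] <- r >= bounds[1L] && r <= bounds[2L]
    }
    if (transient_s > 0 &&
        (centers[j] - half < transient_s ||
         centers[j] + half > duration_s - transient_s)) {
      valid[j] <- FALSE
    }
  }
  structure(
    data.frame(window_center_s = centers, rate = rate,
               n_peaks = n_peaks, valid = valid),
    window_length_s = window_length_s, hop_s = hop_s, kind = kind,
    class = c("rate_series", "data.frame")
  )
}

#' Construct a rate series directly
#'
#' For reference series read from file or built in tests.
#'
#' @param window_center_s window centres in seconds.
#' @param rate rates in events/min.
#' @param kind `"heartbeat"` or `"respiration"`.
#' @param valid logical validity flags (default all `TRUE`).
#' @param window_length_s,hop_s window metadata (defaults 60 and 10 s).
#' @return a `rate_series`.
#' @export
rate_series <- function(window_center_s, rate,
                        kind = c("heartbeat", "respiration"),
                        valid = TRUE, window_length_s = 60, hop_s = 10) {
  kind <- match.arg(kind)
  if (length(window_center_s) != length(rate)) {
    stop_invalid_input("window_center_s and rate must have equal length")
  }
  valid <- rep_len(as.logical(valid), length(rate))
  structure(
    data.frame(window_center_s = as.numeric(window_center_s),
               rate = as.numeric(rate),
               n_peaks = NA_integer_, valid = valid),
    window_length_s = window_length_s, hop_s = hop_s, kind = kind,
    class = c("rate_series", "data.frame")
  )
}

#' Session-level summary of a rate series
#'
#' @param series a `rate_series`.
#' @return list with `median`, `mean` (over valid windows, events/min),
#'   `n_valid`, `n_invalid`, `kind`.
#' @export
session_summary <- function(series) {
  stopifnot(inherits(series, "rate_series"))
  ok <- series$valid & !is.na(series$rate)
  if (!any(ok)) {
    stop_no_valid_data("no valid rate windows in series")
  }
  r <- series$rate[ok]
  list(
    median = stats::median(r),
    mean = mean(r),
    n_valid = sum(ok),
    n_invalid = sum(!ok),
    kind = attr(series, "kind")
  )
}
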