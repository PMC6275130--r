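#' Configuration for the synthetic chest-acceleration generator
#'
#' The simulator emulates the additive structure of a wearable
#' seismocardiogram: total acceleration = low-frequency respiratory
#' oscillation + high-frequency cardiac wavelet train + white Gaussian noise.
#' Respiration is a sinusoid (optionally with up to 3 harmonics) whose
#' amplitude dominates; each heartbeat contributes a Gaussian-windowed
#' sinusoid wavelet, the minimal band-limited pulse whose centre frequency
#' and width are both exposed.
#'
#' Defaults describe a resting adult measured at 50 Hz: heart rate 76
#' beats/min, respiration 20 breaths/min, respiratory amplitude ten times the
#' cardiac amplitude, 4% cycle-to-cycle period jitter and noise at 10% of the
#' cardiac amplitude.
#'
#' @param duration_s recording length in seconds, > 0.
#' @param sampling_rate_hz sampling rate in Hz (default 50).
#' @param heart_rate_bpm true heart rate, beats/min in \[30, 220\].
#' @param resp_rate_brpm true respiration rate, breaths/min in \[2, 60\].
#' @param cardiac_amplitude peak amplitude of a cardiac wavelet, >= 0.
#' @param resp_amplitude amplitude of the respiratory oscillation, >= 0.
#' @param cardiac_wavelet_freq_hz wavelet centre frequency in Hz (default 15);
#'   must exceed `band_cutoff_hz` so cardiac energy lies in the high band.
#' @param cardiac_wavelet_width_s Gaussian envelope standard deviation in
#'   seconds (default 0.08).
#' @param resp_harmonics number of respiratory harmonics (1-3); harmonic k
#'   has amplitude `resp_amplitude / k`.
#' @param rate_jitter_frac cycle-to-cycle period jitter: each inter-beat
#'   period is multiplied by (1 + u), u uniform on \[-frac, +frac\]. In
#'   \[0, 0.5\].
#' @param noise_sd standard deviation of additive white Gaussian noise, >= 0.
#' @param band_cutoff_hz cutoff frequency the downstream band separation will
#'   use (default 0.5 Hz); the configuration is rejected if the cardiac or
#'   respiratory fundamental falls on the wrong side of it.
#' @param seed integer seed; identical configuration + seed gives a
#'   bit-identical trace.
#' @return An object of class `simulation_config` (a validated list).
#' @seealso [simulate_chest_acceleration()]
#' @export
simulation_config <- function(duration_s = 600,
                              sampling_rate_hz = 50,
                              heart_rate_bpm = 76,
                              resp_rate_brpm = 20,
                              cardiac_amplitude = 0.1,
                              resp_amplitude = 1,
                              cardiac_wavelet_freq_hz = 15,
                              cardiac_wavelet_width_s = 0.08,
                              resp_harmonics = 1,
                              rate_jitter_frac = 0.04,
                              noise_sd = 0.01,
                              band_cutoff_hz = 0.5,
                              seed = 1L) {
  cfg <- list(
    duration_s = duration_s, sampling_rate_hz = sampling_rate_hz,
    heart_rate_bpm = heart_rate_bpm, resp_rate_brpm = resp_rate_brpm,
    cardiac_amplitude = cardiac_amplitude, resp_amplitude = resp_amplitude,
    cardiac_wavelet_freq_hz = cardiac_wavelet_freq_hz,
    cardiac_wavelet_width_s = cardiac_wavelet_width_s,
    resp_harmonics = as.integer(resp_harmonics),
    rate_jitter_frac = rate_jitter_frac,
    noise_sd = noise_sd, band_cutoff_hz = band_cutoff_hz,
    seed = as.integer(seed)
  )
  for (f in c("duration_s", "sampling_rate_hz")) {
    if (!is_scalar_number(cfg[[f]]) || cfg[[f]] <= 0) {
      stop_invalid_config(sprintf("'%s' must be a positive number", f))
    }
  }
  if (!is_scalar_number(heart_rate_bpm) ||
      heart_rate_bpm < 30 || heart_rate_bpm > 220) {
    stop_invalid_config("'heart_rate_bpm' must lie in [30, 220]")
  }
  if (!is_scalar_number(resp_rate_brpm) ||
      resp_rate_brpm < 2 || resp_rate_brpm > 60) {
    stop_invalid_config("'resp_rate_brpm' must lie in [2, 60]")
  }
  for (f in c("cardiac_amplitude", "resp_amplitude", "noise_sd")) {
    if (!is_scalar_number(cfg[[f]]) || cfg[[f]] < 0) {
      stop_invalid_config(sprintf("'%s' must be >= 0", f))
    }
  }
  if (!is_scalar_number(rate_jitter_frac) ||
      rate_jitter_frac < 0 || rate_jitter_frac > 0.5) {
    stop_invalid_config("'rate_jitter_frac' must lie in [0, 0.5]")
  }
  if (cfg$resp_harmonics < 1L || cfg$resp_harmonics > 3L) {
    stop_invalid_config("'resp_harmonics' must be 1, 2 or 3")
  }
  if (cardiac_wavelet_freq_hz <= band_cutoff_hz) {
    stop_invalid_config(paste0(
      "band overlap: cardiac_wavelet_freq_hz (", cardiac_wavelet_freq_hz,
      " Hz) must exceed band_cutoff_hz (", band_cutoff_hz,
      " Hz) so cardiac energy lies in the high band"
    ))
  }
  if (resp_rate_brpm / 60 > band_cutoff_hz) {
    stop_invalid_config(paste0(
      "band overlap: respiratory fundamental (", resp_rate_brpm / 60,
      " Hz) must not exceed band_cutoff_hz (", band_cutoff_hz,
      " Hz) so respiratory energy lies in the low band"
    ))
  }
  if (cardiac_wavelet_freq_hz >= sampling_rate_hz / 2) {
    stop_invalid_config("cardiac wavelet frequency must be below Nyquist")
  }
  structure(cfg, class = "simulation_config")
}

#' Simulate a chest-acceleration trace with ground truth
#'
#' Builds the trace as the sum of three parts: a respiratory sinusoid (plus
#' optional harmonics), a train of Gaussian-windowed sinusoid wavelets placed
#' at jittered beat times, and white Gaussian noise. All randomness (period
#' jitter, then noise) flows from `config$seed`, so the same configuration
#' always yields the same trace, and zeroing one component's amplitude leaves
#' the other component and the event schedule untouched.
#'
#' Ground truth records beat times (wavelet centres), breath times (maxima of
#' the respiratory fundamental) and the nominal true rates, for recovery
#' tests against the estimation chain.
#'
#' @param config a [simulation_config()].
#' @return list with elements `trace` (an [acceleration_trace()]) and
#'   `ground_truth` (list: `beat_times_s`, `breath_times_s`, `true_hr_bpm`,
#'   `true_rr_brpm`).
#' @examples
#' sim <- simulate_chest_acceleration(simulation_config(duration_s = 60))
#' sim$trace
#' head(sim$ground_truth$beat_times_s)
#' @export
simulate_chest_acceleration <- function(config) {
  if (!inherits(config, "simulation_config")) {
    stop_invalid_config("'config' must be a simulation_config object")
  }
  n <- round(config$duration_s * config$sampling_rate_hz)
  t <- (seq_len(n) - 1L) / config$sampling_rate_hz

  with_local_seed(config$seed, {
    # -- beat schedule (drawn first so it is amplitude-independent) --
    period <- 60 / config$heart_rate_bpm
    # generous upper bound on the number of beats, then trim to duration
    n_max <- ceiling(config$duration_s / (period * (1 - config$rate_jitter_frac))) + 2L
    jit <- if (config$rate_jitter_frac > 0) {
      stats::runif(n_max, -config$rate_jitter_frac, config$rate_jitter_frac)
    } else {
      rep(0, n_max)
    }
    beat_times <- period / 2 + cumsum(c(0, period * (1 + jit[-1L])))
    beat_times <- beat_times[beat_times <= config$duration_s]

    # -- respiratory component --
    f_r <- config$resp_rate_brpm / 60
    resp <- numeric(n)
    if (config$resp_amplitude > 0) {
      for (k in seq_len(config$resp_harmonics)) {
        resp <- resp + (config$resp_amplitude / k) * sin(2 * pi * k * f_r * t)
      }
    }
    breath_times <- (seq(0.25, by = 1, length.out = ceiling(config$duration_s * f_r) + 1L)) / f_r
    breath_times <- breath_times[breath_times <= config$duration_s]

    # -- cardiac component: Gaussian-windowed sinusoid per beat --
    card <- numeric(n)
    if (config$cardiac_amplitude > 0 && length(beat_times)) {
      sigma <- config$cardiac_wavelet_width_s
      half <- ceiling(4 * sigma * config$sampling_rate_hz)
      for (bt in beat_times) {
        ic <- round(bt * config$sampling_rate_hz) + 1L
        idx <- max(1L, ic - half):min(n, ic + half)
        dt <- t[idx] - bt
        card[idx] <- card[idx] + config$cardiac_amplitude *
          exp(-dt^2 / (2 * sigma^2)) *
          sin(2 * pi * config$cardiac_wavelet_freq_hz * dt)
      }
    }

    noise <- if (config$noise_sd > 0) stats::rnorm(n, 0, config$noise_sd) else numeric(n)

    list(
      trace = acceleration_trace(resp + card + noise,
                                 config$sampling_rate_hz),
      ground_truth = list(
        beat_times_s = beat_times,
        breath_times_s = breath_times,
        true_hr_bpm = config$heart_rate_bpm,
        true_rr_brpm = config$resp_rate_brpm
      )
    )
  })
}
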