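# Shared fixtures: simulation + estimation shortcuts and a spectral oracle.

sim_trace <- function(..., seed = 7) {
  simulate_chest_acceleration(simulation_config(..., seed = seed))
}

# session-median recovery for one simulated condition
recover_rates <- function(hr, rr, noise_sd = 0, duration_s = 300, seed = 7) {
  sim <- sim_trace(duration_s = duration_s, heart_rate_bpm = hr,
                   resp_rate_brpm = rr, noise_sd = noise_sd, seed = seed)
  bands <- separate_bands(sim$trace)
  hr_est <- session_summary(rate_from_peaks(
    detect_peaks(bands$cardiac, "heartbeat"),
    duration_s = duration_s, transient_s = 5))$median
  rr_est <- session_summary(rate_from_peaks(
    detect_peaks(bands$respiratory, "respiration"),
    duration_s = duration_s, transient_s = 5))$median
  c(hr = hr_est, rr = rr_est)
}

# fraction of discrete-Fourier energy at frequencies strictly below f_split
energy_fraction_below <- function(x, fs, f_split) {
  n <- length(x)
  mag2 <- Mod(stats::fft(x))^2
  freq <- (seq_len(n) - 1L) * fs / n
  # fold: keep 0..Nyquist only (two-sided spectrum is symmetric)
  keep <- freq <= fs / 2
  sum(mag2[keep & freq < f_split]) / sum(mag2[keep])
}

# amplitude of a steady tone measured away from filter edge transients
# (RMS-based: sqrt(2)*RMS is exact for whole half-cycles and immune to the
# sample grid missing the sinusoid crest)
mid_amplitude <- function(samples, fs, edge_s = 5) {
  i <- (edge_s * fs):(length(samples) - edge_s * fs)
  sqrt(2 * mean(samples[i]^2))
}
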