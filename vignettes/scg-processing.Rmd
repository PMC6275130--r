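---
title: "Methods: from chest acceleration to rates and a health statistic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from chest acceleration to rates and a health statistic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scgpipe)
```

## The signal model

A single-axis accelerometer worn between chest and abdomen records the sum
of two physiological motions plus noise:

\[ a_T(t) = a_L(t) + a_H(t) + \varepsilon(t) \]

where \(a_L\) is the lung-driven oscillation — large amplitude, below the
respiratory fundamental of at most 0.5 Hz — and \(a_H\) is the train of
short cardiac vibrations (the seismocardiogram proper) whose energy sits
well above 1 Hz. Everything in this package follows from that additive,
spectrally disjoint structure: the two components can be split by linear
filtering, each band yields an event train, each event train yields a rate
series, and the *distribution* of those rates carries diagnostic
information beyond the rates themselves.

## Band separation

`separate_bands()` applies a second-order high-pass and a second-order
low-pass Butterworth filter sharing one physical cutoff, 0.5 Hz by default
at a 50 Hz sampling rate. Only the high-pass order is fixed by the
acquisition design this package mirrors; the low-pass is taken symmetric at
the same order, and both cutoff and order are configurable. Two
normalization conventions for quoting the cutoff circulate (0.5 Hz at 50 Hz
is 0.01 of the sampling rate but 0.02 of Nyquist); `normalized_cutoff()`
exposes both, while all design code works from the physical cutoff in Hz.

Offline processing defaults to forward–backward (zero-phase) filtering:
rate estimation depends on peak *timing*, and a causal second-order filter
at 0.5 Hz would delay the respiratory band by a substantial fraction of a
second. The price is that the effective magnitude response is the square of
the single-pass response; the tests account for this. A `causal_streaming`
mode applies one pass for parity with on-line use.

The bilinear transform used in digital Butterworth design pre-warps at the
cutoff, so the −3 dB point is exact; away from the cutoff the realized
magnitude follows the analog form \(1/\sqrt{1+(f/f_c)^{2n}}\) only up to
frequency warping, which grows as frequencies approach Nyquist (6.5% low at
\(10 f_c\) when \(f_s = 50\) Hz). Tests that use the analog closed form as
an oracle therefore evaluate designs whose cutoff sits far below Nyquist;
tests at 50 Hz compare against the warped closed form.

The first and last 5 s of the filtered output are flagged — not removed —
as edge transients (a second-order 0.5 Hz filter settles well within that),
and rate windows overlapping the flags are marked invalid.

## Event detection

The package deliberately uses different detectors per band, because the two
waveforms are opposites: the cardiac band is a sparse train of
high-frequency wavelets on a near-zero baseline, the respiratory band is a
continuous slow oscillation.

**Heartbeat.** Detection runs on an RMS envelope. The band is first
detrended by subtracting a 0.3 s centred moving average: a second-order
high-pass at 0.5 Hz passes roughly 40% of a 0.33 Hz respiratory fundamental
(and half of one at the cutoff itself), and with a 10:1
respiratory-to-cardiac amplitude ratio that leakage would otherwise exceed
the cardiac signal. The moving average tracks anything slower than ~2 Hz
and leaves a 15 Hz wavelet essentially untouched, so subtracting it removes
the leakage at negligible cost. The envelope is then the root of a 0.15 s
moving mean of squares; its maximum over a wavelet falls at the wavelet
centre, so peak times estimate beat times directly. Candidate peaks are
strict local maxima of the envelope that (a) exceed `threshold_k` (default
1.5) times the envelope's rolling standard deviation over a 5 s window and
(b) exceed half the rolling envelope maximum over the same window. The
second gate is scale-free and rejects what the first cannot: between-beat
noise bumps and residual leakage sit well below half the local beat
envelope at any heart rate, while the SD gate alone drifts with duty cycle.

**Respiration.** The respiratory band is close to a sinusoid, and a
sinusoid's peaks rise only \(\sqrt{2}\approx 1.41\) standard deviations
above its mean — a threshold of 1.5 signal-SDs would reject every breath,
at any amplitude. The threshold is therefore scaled by a rolling *noise*
estimate instead: the standard deviation, over the same 5 s window, of the
residual after subtracting a 1 s moving average — i.e. of whatever in the
band is too fast to be breathing. A candidate maximum is kept when it rises
more than `threshold_k` noise-SDs above the rolling mean.

Both detectors break ties between equal-height neighbours toward the
earliest sample (the envelope is snapped to 12 significant digits first, so
plateaus arising from discrete windows are exact ties rather than
floating-point accidents), and both finish with a refractory pass in which
the larger of any two detections closer than the refractory period
survives. The refractory defaults are physiological ceilings, not tuning
constants: 0.27 s corresponds to 220 beats/min, 1.0 s to 60 breaths/min.

The detector assumes its channel actually contains the target signal: fed
pure noise, the envelope gates scale down with the noise and detections
will appear. There is no signal-presence test; absence of cardiac or
respiratory activity shows up downstream as out-of-bound or wildly
dispersed rate windows, not as an empty peak list (a strictly flat channel
does return no peaks).

## Rate estimation

`rate_from_peaks()` slides a 60 s window by 10 s and estimates the rate in
each window as 60 divided by the *median* inter-peak interval. The median
is preferred to peak counting because a single missed event doubles one
interval but barely moves the median, while counting is off by one per
miss. Windows with fewer than two peaks, rates outside the physiological
bounds (heartbeat 30–220 beats/min, respiration 2–60 breaths/min), or
overlap with the filter-transient flags are carried with `valid = FALSE` —
never dropped, so window provenance is preserved. At a 50 Hz sampling rate
peak times are quantized to 20 ms, which bounds the rate quantization at
~1 bpm around 76 bpm; session medians inherit that granularity.

## The healthy measure

Sessions are summarised by the shape of the rate distribution: its length
\(L\) (span of observed rates) and height \(h\) (windows in the most
populated bin), combined as

\[ \text{measure} = L / h . \]

A steady rate gives a short, tall distribution and a small measure; a
disordered one gives a long, flat distribution and a large measure. "Length"
and "height" of a distribution plot admit more than one reading; the
default here is empirical — observed range and modal count of a
1-rate-unit histogram — which is the only reading consistent with
integer-valued published examples (length 17, height 10 for a healthy
subject's heartbeat, measure 1.7). A normal-fit variant
(\(L = 2z\sigma\) with \(z = 2\) by default, \(h\) the expected modal-bin
count) is provided, and the convention used is recorded in every output.
The defining equations of the measure are printed in the source literature
with crossed subscripts (each signal's measure defined from the other
signal's length and height); this package uses the self-consistent
per-signal reading, which matches the published worked example.

Classification is a step function with two borders per signal kind;
boundary values belong to the more severe class. Published per-class
measures (heartbeat 1.7 / 5.56 / 9.88; respiration 1.54 / 1.9 / 2.3) fix
only three points, not the borders, so the defaults are consecutive
midpoints — heartbeat 3.63 and 7.72, respiration 1.72 and 2.10 — fully
configurable and carrying no claim of clinical validity.

## Agreement statistics

`bland_altman()` computes, for differences \(d = \text{test} -
\text{reference}\): the mean error, the sample (n−1) standard deviation,
95% limits of agreement mean ± 1.96 SD, and RMSE. The identity
\(\mathrm{RMSE}^2 = \bar d^{\,2} + s_d^2 (n-1)/n\) holds exactly and is
property-tested. Series are paired by nearest window centre with a maximum
offset of half a hop; unmatched windows are counted, not silently dropped.

## The simulator, and what passing tests mean

`simulate_chest_acceleration()` builds traces with exactly the additive
structure above: a respiratory sinusoid (optionally up to three harmonics),
Gaussian-windowed 15 Hz sinusoid wavelets of 0.08 s width at jittered beat
times, and white Gaussian noise, all driven by one seed. Defaults describe
a resting adult at the acquisition design's own operating point: 600 s at
50 Hz, 76 beats/min, 20 breaths/min, a 10:1 respiratory-to-cardiac
amplitude ratio (the literature states only that the respiratory
acceleration is larger), 4% cycle-to-cycle period jitter, and noise at 10%
of the cardiac amplitude. Amplitudes are unit-agnostic ("accel units")
because the source work never fixes g versus m/s².

The respiratory fundamental may equal the band cutoff (30 breaths/min at
0.5 Hz) — half the amplitude still reaches the low band and peak timing is
unaffected — but configurations above the cutoff, or with cardiac wavelets
at or below it, are rejected as band-overlap errors.

The simulator emulates spectral structure, amplitude ordering, rate jitter
and sensor noise. It does **not** emulate motion artefacts, posture
changes, heartbeat morphology variation, amplitude modulation of cardiac
vibrations by respiration, or non-white sensor noise. Recovery results on
synthetic data therefore demonstrate the correctness of the chain under its
own model assumptions — not clinical performance on worn-sensor
recordings, whose error statistics can only be bounded, not reproduced, at
the desk.

## Numerical and testing choices

* Rolling mean/SD are exact cumulative-sum forms (population SD) with
  truncated windows at the edges; the rolling maximum uses an O(n)
  two-pass block scheme.
* Recovery tests use 300 s sessions across a grid of 50–150 beats/min by
  5–30 breaths/min, and 600 s for the rest-scenario and end-to-end
  agreement checks; session medians are compared within ±2 beats/min and
  ±1 breaths/min (±5 beats/min with noise at 20% of the cardiac
  amplitude).
* Reports serialize with `jsonlite` at full precision and contain no
  timestamps, so identical trace + configuration yields byte-identical
  JSON.
* Trace CSVs are written with 17 significant digits so write→read round
  trips are exact; readers validate monotone, uniform (≤1% period jitter)
  time axes and report the offending line otherwise.

## Known limitations

* Rates below the window's two-peak minimum (respiration slower than
  2 breaths/min per 60 s window) are unmeasurable by construction.
* The class borders interpolate three published points; they are
  illustrative defaults, not validated thresholds.
* Streaming mode documents but does not compensate group delay; peak
  timing comparisons should use zero-phase mode.
* With no motion-artefact model, the detector's robustness claims extend
  only to additive white noise.
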