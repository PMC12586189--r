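---
title: "Quantifying respiratory heart rate variability: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying respiratory heart rate variability: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resphrv)
```

## The measurement

Respiratory heart rate variability (RespHRV; the respiratory sinus
arrhythmia) is the cyclic acceleration of the heart during inspiration and
slowing during expiration, driven by respiratory gating of cardiac
parasympathetic outflow. The package quantifies it by
**respiratory-triggered averaging**: the instantaneous heart rate series is
cut into respiratory cycles at successive end-inspiration times, each cycle
is resampled onto a common phase grid (`n_bins = 100` by default), and the
grid is averaged across cycles. The RespHRV amplitude is the max − min of
that average; the mean heart rate (mHR) is the time average of the
instantaneous HR over the same analysis window.

Two conventions matter and are fixed throughout:

* **Piecewise-constant HR.** `instantaneous_hr()` holds `60/RR` constant
  over each inter-beat interval. This matches the event nature of beat
  timing and makes degenerate cases exact: constant beat spacing gives an
  exactly constant HR, and a square HR modulation aligned with exact cycles
  is recovered bin-exactly.
* **Phase-normalized averaging.** Respiratory periods vary cycle to cycle
  (`frequency_cv > 0`); averaging in normalized phase rather than fixed
  time prevents the expiratory trough from smearing. The trigger is
  end-inspiration, taken from the breath train itself rather than assumed
  at a fixed fraction of the cycle.

Cycle-count policies mirror standard practice per preparation
(`condition_policy()`): at least 40 cycles for freely moving mice, 15 for
anesthetized preparations and the working heart–brainstem preparation, and
100 for stress/telemetry sessions. When a window holds fewer complete
cycles the average is refused with an explicit shortfall message rather
than silently computed.

## Finite-beat-sampling attenuation and its correction

A mouse at 532 bpm breathing at 125 cycles/min has only ~4.3 heartbeats per
breath. Under the piecewise-constant convention each instant carries the
*mean* rate of its enclosing RR interval, so the triggered average is the
true modulation convolved with (approximately) a triangular kernel of
half-width `w = RR/period` in cycle units. The fundamental of the
modulation is attenuated by `sinc²(πw)` — about 0.83 at the rates above —
so the raw max − min underreads the modulation depth of the underlying
cardiac rate by roughly 17%.

The raw value is the conventional reported amplitude and remains the
default. When the goal is the underlying modulation depth (e.g. parameter
recovery against the generator), `resphrv_amplitude(ta, correct_sampling =
TRUE)` divides each Fourier harmonic of the binned average by the kernel
transmission `sinc²(πhw)`, keeping only harmonics transmitted with gain at
least `min_transmission` (default 0.5, so noise is never amplified more
than two-fold) and reconstructing the waveform from those. `w` is estimated
from the window's own mean HR and mean respiratory period. With the
near-sinusoidal modulation the generator produces, the fundamental carries
essentially all the depth, and the correction is exact up to sampling
noise; for strongly non-sinusoidal modulation at very low beats-per-breath
the dropped harmonics make the corrected value a lower bound. In the
fine-sampling regime (≥ ~20 beats per breath) raw and corrected values
agree within a couple of percent, which is how the test suite checks the
noiseless identity between the set depth and the measured amplitude.

`epoch_metrics()` reports both `resphrv` (raw) and `resphrv_corrected`.

## The synthetic-data generator

The generator exists to give every stage a ground truth; its defaults are
the study conditions of a freely moving mouse at rest.

* **Breath train** (`resp_params()`): cycle periods drawn around
  `60/base_frequency` (default 125 cycles/min awake; set lower for
  anesthetized or slice rhythms) with coefficient of variation 0.1,
  truncated at 20% of the mean; inspiration occupies a fixed fraction of
  each cycle (default 0.35); amplitudes have mean 1 a.u. and CV 0.1.
* **Heartbeats** (`cardiac_params()`, `simulate_beats_ipfm()`): integral
  pulse frequency modulation. The instantaneous rate is
  `m(t) = base_hr + mhr_shift + gain·D·s(φ(t)) + ε(t)`, with `D =
  resp_mod_depth` (default 13.2 bpm on a 532 bpm base), `s` a zero-mean
  raised cosine with peak-to-trough 1 peaking at mid-inspiration, and
  `ε` white Gaussian noise (SD 10 bpm per sample at the 1 kHz integration
  grid; after averaging over one RR interval this leaves ~0.5 bpm of
  beat-to-beat rate noise, a conservative stand-in for non-respiratory
  HRV). A beat fires whenever `∫ m/60 dt` crosses an integer, so a constant
  rate yields intervals of exactly `60/m` — the closed form the test suite
  checks at machine precision. The full-cycle cosine was chosen over a
  bump confined to inspiration because its single harmonic makes the
  sampling-kernel correction exact; `gain` multiplies the depth and models
  the oxytocinergic amplification of RespHRV, and `mhr_shift` the
  accompanying mean-rate change. HR noise is added to the rate, not to the
  intervals, which keeps triggered averaging unbiased. The
  cardio-respiratory latency is a configurable fixed lag, default 0 — a
  convention, since only qualitative phase alignment is reported for the
  preparations emulated.
* **Channels.** ECG: a stereotyped 40 ms QRS template at each beat
  (overlapping templates are refused). Plethysmography: each cycle rises
  over inspiration as a raised cosine to its peak at end-inspiration,
  falls over an equal early-expiratory interval, and stays at baseline for
  late expiration — as in chamber-pressure recordings where expiratory
  flow ends well before the next breath. The locally symmetric peak is
  deliberate: it makes end-inspiration estimable without bias by a local
  parabola. Nerve kinds: phrenic-like inspiratory bursts,
  cardiac-vagal-like tonic activity with multiplicative respiratory
  modulation minimal in inspiration, and inhibitory-current volleys during
  inspiration. Channel noise defaults give SNR 10 on ECG and
  plethysmography.
* **Sessions** (`build_session()`): epoch schedules change parameters
  stepwise at epoch boundaries (no ramps — the simplest testable
  contract). Bundled protocols: `protocol_photostim()` (60 s baseline,
  60 s stimulation with gain 1.5 and −35 bpm shift, 60 s recovery;
  analysis in the final 30 s of each epoch, where stimulation effects are
  maximal and stable) and `protocol_stress()` (10 min baseline, 10 min
  restraint with gain 0.5 and +80 bpm, recovery probed at 25–35 and
  55–65 min post stress, stress effects in the first 5 min; the
  `immediate`/`delayed` variants restore the gain 10 vs 50 min after the
  restraint ends).

What the generator does **not** emulate: ECG morphology beyond the QRS
complex, ectopy and arrhythmia, movement artifacts, baseline wander beyond
what the detectors' rolling baselines are tested against, blood-pressure
waveform shape, and any dependence of respiratory frequency on state
beyond the stepwise schedules. Passing the recovery tests therefore shows
the estimator chain is correct and well-calibrated under these idealized
conditions, not that detection is robust to every artifact of real
recordings.

## Event detection

* `detect_beats()`: local maxima of the baseline-removed (1 s rolling
  median), lightly smoothed signal exceeding `threshold_fraction` (0.5) of
  a rolling amplitude estimate — the max over a 2 s trailing window,
  mirrored with a leading window so the recording edges see a beat —
  separated by a refractory period (30 ms default, mouse-scale;
  configurable for rat/WHBP). The 5 ms pre-smoothing acts as a crude
  matched filter; peak times are refined by three-point parabolic
  interpolation to sub-sample precision. When two candidates fall within
  one refractory period the larger wins.
* `segment_breaths()`: cycle onsets at upward zero crossings of the
  smoothed, baseline-removed signal; end-inspiration at the intra-cycle
  maximum, refined by a least-squares parabola over ±60 ms (unbiased for
  locally symmetric peaks; the window averages noise down to ~2 ms timing
  error at SNR 10); cycles shorter than `min_cycle` are merged. Inspiration
  is the positive deflection; `invert` handles the opposite dialect.
* `detect_bursts()`: contiguous regions above the rolling-median baseline
  plus `threshold_sd` robust SDs (MAD of the residual), minimum duration
  50 ms, gaps under `min_interval` merged. The baseline window (1 s) must
  exceed twice the longest burst, which holds for the inspiratory bursts
  emulated here.

Detection thresholds were calibrated on synthetic data only; the
Spike2-style manual verification step of bench practice has no equivalent
here.

## Nerve and slice metrics

`respiratory_modulation()` applies the triggered-averaging machinery to an
integrated nerve signal; the percent modulation is normalized to the epoch
mean by default. Whether such percentages should instead be normalized to a
baseline-epoch modulation amplitude is genuinely ambiguous in the
literature this emulates, so the alternative is exposed as
`normalize = "baseline"` with an explicit reference amplitude.

`synaptic_drive()` rectifies the current trace about its median (outward,
inhibitory currents positive; a sign flag handles the opposite clamp
convention), low-pass filters it at 10 Hz — first-order zero-phase
Butterworth, chosen because its monotonic step response cannot overshoot a
square volley, and 10 Hz separates the volley envelope from spiking
texture at slice time scales — and takes each burst's maximal envelope
minus a pre-burst baseline, averaged over the first ten consecutive bursts
of the trace (earliest-first is the deterministic reading of "ten
consecutive bursts"). Subtracting the median before filtering makes the
result exactly invariant to a constant holding current.

## Effect statistics

`epoch_delta()` computes `Δ = post − pre` and `Δ% = 100·(post − pre)/pre`;
`report_delta()` applies the integer rounding used at the reporting layer
while full precision is kept internally. For group summaries two
conventions exist: the mean of per-subject deltas and the delta of group
means. Printed group Δ% values in this literature are arithmetically
consistent only with per-subject averaging (a 13.2 → 19.5 group-mean change
is +48% as a delta of means), so `group_effect()` defaults to
`per_subject_mean`; both conventions are first-class and labelled in the
output. `pearson_regression()` is the standard product-moment r with a
two-sided p from the t transform on n − 2 degrees of freedom plus the
least-squares line. `recovery_kinetics()` declares recovery at the first
timed bin whose |Δ%| versus the pre-stress baseline falls within a
criterion band (10% default).

`stability_profile()` — sliding-window RespHRV amplitudes flagged stable
when their coefficient of variation is below a bound — is this package's
own windowed-stability metric, documented as such; it is not a published
procedure.

## Numerical choices and degenerate inputs

* IPFM integration uses zero-order-hold cumulative sums with linear
  crossing interpolation; a `1e-9` guard absorbs floating-point shortfall
  at integer boundaries, and constant-rate intervals are exact to
  ~1e-15 s.
* Flat signals yield empty event sets with warnings, not errors; rates
  driven non-positive, overlapping QRS templates, unknown channel kinds or
  parameter overrides, zero-variance correlations and zero-baseline
  percentages are refused with typed conditions
  (`resphrv_invalid_argument`, `resphrv_invalid_params`,
  `resphrv_shortfall`, `resphrv_parse_error`).
* Epochs are half-open `[start, end)` in seconds from recording start, so
  cycle membership is unambiguous; all generators are bit-reproducible
  under a fixed seed, and `run_pipeline()` embeds a configuration hash in
  its output.

## Problem sizes used by the test suite

The suite exercises the full pipeline at the sizes the analyses are meant
for: 180 s freely-moving sessions (≈ 370 breaths, ≈ 1600 beats) across 20
seeds for parameter recovery; four gains x 20 seeds at 120 s each for
monotonicity; 85 min stress sessions (event-level, 400–500 Hz integration
grid) x 2 fixtures x 20 seeds for recovery kinetics; and small randomized
instances for the brute-force oracle comparisons. `scripts/acceptance.R`
re-runs the same computations from scratch and writes the headline numbers
as JSON.

## Known limitations

* The sampling-kernel correction assumes the modulation is dominated by
  harmonics the kernel transmits; at very low beats-per-breath it cannot
  restore sharper waveform features, and it presumes the IPFM-like
  relationship between beat intervals and the underlying rate.
* End-inspiration timing accuracy depends on the plethysmographic peak
  being locally symmetric at the smoothing scale; strongly skewed peaks
  will incur a systematic (but cycle-consistent, hence
  amplitude-harmless) offset.
* No frequency-domain HRV, Poincaré or entropy metrics, no arrhythmia
  handling, no apnea scoring, and no omnibus group testing — the metrics
  tables are designed to be consumed by external statistics tooling.
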