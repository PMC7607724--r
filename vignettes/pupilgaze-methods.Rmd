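---
title: "Methods: pupillometry, microsaccades, and within-subject statistics in pupilgaze"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pupillometry, microsaccades, and within-subject statistics in pupilgaze}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupilgaze)
```

`pupilgaze` analyses task-evoked pupillometry from sentence-listening
experiments with a 2×2 within-subject design: a *Clarity* factor (speech at
a high vs. a low signal-to-noise ratio, or clear vs. masked) crossed with an
*Ambiguity* factor (sentences containing several semantically ambiguous
words vs. matched unambiguous sentences). This vignette describes the
models and procedures, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical
choices made where the design was genuinely open.

## The single-trial pupil chain

A trial's recording spans a 3 s pre-onset lead, the sentence (1.4–4.8 s),
and a 1.2 s post-offset tail, sampled at 500 Hz; time is expressed in
seconds relative to sentence onset, so every analysis window below is
onset- or offset-anchored. The chain, in order:

1. **Blink blanking.** For each interval the tracker flags as a blink,
   pupil samples from `blink_pre_s = 0.05` s before its start to
   `blink_post_s = 0.20` s after its end are set to `NaN` (closed interval
   on the sample grid). The pipeline deliberately does *not* re-detect
   blinks from the pupil signal: blink annotation is the device's job.
2. **Robust outlier blanking.** Samples whose pupil area differs from the
   trial median by more than `mad_k = 3` times the *raw* median absolute
   deviation are set to `NaN`. The MAD carries no 1.4826 normal-consistency
   factor, and the statistics are computed over the whole recorded trial,
   after blink blanking (so blink garbage cannot corrupt them). The
   comparison is strict (`>`), so a constant trace (MAD = 0) loses nothing.
3. **Linear interpolation.** Interior `NaN` runs are bridged linearly
   between the bracketing finite samples; leading/trailing runs are filled
   by constant extension of the nearest finite value.
4. **Trial exclusion.** On the *pre-interpolation* missing mask, the
   fraction of `NaN` samples with `t ∈ [−0.5 s, offset + 1 s]` is computed;
   the trial is excluded iff this fraction strictly exceeds
   `nan_frac_max = 0.40`. The pre-interpolation mask is the only mask on
   which a "percentage of missing entries" is well defined. Excluded trials
   skip the remaining stages. A trial left with fewer than two finite
   samples is excluded outright.
5. **Low-pass filtering.** A 201-tap linear-phase FIR, designed by the
   Kaiser-window method (β = 5, ≈ 50 dB sidelobes; β is configurable since
   only cutoff and length are canonical), cutoff 10 Hz. The symmetric
   filter is applied centred — group delay compensated — with reflection
   padding at the edges, and the taps are normalized to a DC gain of
   exactly 1. Zero net phase matters because peak *latency* is a dependent
   measure; a causal filter would bias it by 200 ms.
6. **Baseline correction.** The mean over the closed-open window
   `[−0.5 s, 0 s)` is subtracted from every sample (closed-open so the
   onset sample is not counted in both baseline and response). After this
   stage the baseline-window mean is 0 to 1e−9 a.u. by construction.

Three dependent measures are extracted per trial over the window from
`0.5` s after onset to `1` s after offset: the **mean dilation**, the
**peak dilation** (maximum of the corrected trace), and the **peak
latency** (time of that maximum, first occurrence on ties, reported
relative to sentence onset; reporting relative to the window start would
shift every value by a constant 0.5 s and change no test statistic).
Behavioral accuracy is the proportion of correct semantic-relatedness
responses; response timeouts are scored incorrect by default
(`none_policy = "incorrect"`), since a participant who cannot answer within
the deadline has not demonstrated comprehension — a configurable choice, as
scoring of timeouts is genuinely open.

Trial values are averaged per participant and condition cell into a
participant × {LA_high, HA_high, LA_low, HA_low} table; participants
missing a cell entirely are dropped listwise (a repeated-measures ANOVA
needs complete cells).

## Microsaccade detection and rate

Gaze position is differentiated with the standard 5-point moving-window
stencil, `v_i = (p_{i+2} + p_{i+1} − p_{i−1} − p_{i−2}) / (6Δt)`, which is
exact for quadratics and suppresses sampling noise. Per component, the
noise scale is the median-based robust estimator
`σ² = median(v²) − median(v)²`, and the threshold is `η = 15σ` — a
*relative* threshold, so detection is invariant to affine changes of gaze
units. A configurable floor (`ms_velocity_floor_deg_s = 0.01` deg/s)
prevents a zero threshold on noise-free synthetic data. Whether the
literature's multiplier sits on the median-estimator scale or on a plain
standard deviation is ambiguous; the median estimator is the convention of
the velocity-threshold detection family this implements, and the scalar
`criterion = "speed"` variant is available as a config switch next to the
default two-component elliptic criterion `(vx/ηx)² + (vy/ηy)² > 1`.

Maximal runs of suprathreshold samples persisting at least
`ms_min_duration_s = 0.006` s (a k-sample run persists kΔt) become events;
runs inside expanded blink windows are discarded. No merging of events
across sub-threshold gaps is performed (no merge rule is canonical).
Each event contributes a unit-area Gaussian (SD `0.02` s, zero phase lag)
centred at its *onset* (timestamping at onset vs. midpoint is a config
switch) to the trial's rate curve, in events/s; the mean rate over the
sentence-locked metric window is the trial's dependent measure. Note that a
brief but violent excursion is smeared by the 5-point stencil: the 6 ms
persistence rule therefore rejects short *glitches* whose suprathreshold
velocity samples do not form a contiguous run, which is its purpose.

## Acoustic masker constructions

All maskers operate on in-memory mono waveforms (`waveform(samples, rate)`).

* **Babble**: the sentence set is concatenated in `n_streams = 30`
  independent random orders, streams are truncated to the shortest and
  averaged samplewise — yielding the materials' long-term spectrum with a
  flattened envelope. Averaging N near-independent streams scales the RMS
  by ≈ 1/√N; with a *small* sentence set the streams align identical
  material often enough to break that approximation, which is why the test
  suite uses 50 sentences.
* **Envelope-modulated pink noise**: the target's amplitude envelope is the
  magnitude of its FFT-based analytic (Hilbert) signal, low-pass filtered
  at 30 Hz with a zero-phase (forward–backward) Butterworth of order 4
  (order and phase handling are open choices; zero phase avoids skewing the
  envelope), then applied samplewise to spectrally synthesized 1/f noise.
  The envelope routine reflects ~100 ms of signal at each end so FFT
  wrap-around and filter transients fall in the padding.
* **SNR mixing**: SNR is the RMS power ratio in dB over the common span —
  the field convention — and the designated component (target or masker) is
  rescaled so the re-measured SNR hits the request exactly (tested to
  1e−6 dB). Study levels are +6, 0 and −2 dB.
* **Framing**: the masker runs from 3 s before sentence onset to 1.2 s
  after offset with 10 ms linear on/off ramps (ramp shape unspecified in
  the source procedures; linear is the simplest monotone choice). Sample
  counts are exact: `round(lead·fs) + n + round(tail·fs)`.
* **RMS normalization** matches stimuli in root-mean-square level.

## Statistics

All within-subject tests reduce to per-participant contrast scores: for a
2-level factor the score is the difference of the participant's level
means; for the interaction, the double difference. The test is then the
one-sample F on the scores, `F(1, n−1) = t²`, with
`ηp² = SS_eff / (SS_eff + SS_err) = F / (F + df_den)`. With two-level
factors sphericity holds trivially, so no correction is applied. Zero-variance
score vectors (possible in degenerate simulations) report `F = 0, p = 1`
with a warning rather than `NaN`, keeping simulation sweeps total.

Pooling two experiments uses the classical split-plot partition:
per-participant grand means test the between-subjects Experiment factor
against between-subject error; each within contrast and its ×Experiment
crossing are tested against the pooled within-group variance of that
contrast, all with `N − 2` denominator df. Group means enter with equal
weight (the least-squares convention; identical to the classical partition
for equal group sizes). The "is the Clarity effect larger than the
Ambiguity effect" question is implemented as a one-sample F on
`d_C − d_A` (signed scores by default; `abs_effects = TRUE` compares
magnitudes), since the contrast construction itself is not canonical.
Partial correlations residualize both variables on `[1, covariate]` and use
`df = n − 3`.

The simple-effect error term is the per-level paired error (the paired t on
the two cells at the fixed level), not a pooled term — the more robust
choice when variances differ between levels.

## The synthetic-data generator

`simulate_experiment()` emulates the study design: per participant, 4
blocks × 28 trials (7 per cell), with block-wise pseudorandom orders
rejecting runs of more than 3 equal-ambiguity or 2 equal-clarity trials
(bounded rejection sampling, 10,000 tries; uniformity over admissible
orders is not claimed, only constraint satisfaction — the constraint, not
the sampler, is canonical).

The pupil model is
`pupil(t) = tonic + drift + slow(t) + A·s(t) + ε(t)`, where `s` is a
sentence-long boxcar convolved with the two-parameter gamma-family pupil
impulse response `h(t) ∝ t^n e^{−nt/t_max}` (n = 10.1, t_max = 0.93 s —
the field's standard surrogate; the emulated study specifies no response
model) and normalized to unit peak for the trial's duration, so the
amplitude `A` *is* the evoked peak in tracker units. `A` sums a base
(30 a.u.), condition effects (`beta_clarity = 12`, `beta_ambiguity = 6`,
`beta_interaction = −4`, i.e. mildly subadditive), a participant offset
(SD 10) and trial jitter (SD 8). `slow(t)` is a random walk whose
end-of-trial deviation has SD `slow_sd = 60` a.u.: real recordings are
dominated by slow spontaneous fluctuations, and without them the trial MAD
collapses and the 3×MAD rule would clip the evoked response itself — with
this component, simulated exclusion (~1.5% of trials) and interpolation
(~5% of samples) land near the percentages seen in practice. White noise
(SD 15) and a linear drift (total SD 15) complete the trace. Blinks are
Poisson-placed (0.05 events/s, 0.1–0.3 s) NaN intervals, a rare long
closure (p ≈ 0.015, 2–4 s) produces realistically excluded trials, and
isolated ±300 a.u. spikes (0.2 events/s) exercise the outlier rule.
All amplitude-scale defaults are stand-ins in arbitrary tracker units,
chosen once for realism — the study reports no effect sizes in such units.

Gaze is white fixational noise (SD 0.005°) with superposed ballistic
microsaccades: raised-cosine velocity profiles, amplitudes 0.1–1°,
durations 10–25 ms (amplitude and duration drawn independently, which
induces the approximately linear amplitude/peak-velocity main sequence
`v_peak = 2A/d`), directions uniform, onsets from an inhomogeneous Poisson
process (base 1.5 events/s) with a rectangular post-onset inhibition
(depth 0.7 for 0.5 s) so cohort-average rate curves show the
inhibition-then-recovery signature. Behavioral responses are Bernoulli
draws at per-cell accuracies (defaults 0.92/0.93/0.89/0.83, emulating
high-but-imperfect comprehension that worsens for ambiguous sentences at
low SNR), with a 1% timeout rate.

What the generator does **not** emulate: pupil foreshortening with gaze
position, binocular data, saccade-locked transient pupil responses, drift
or tremor microstructure in gaze, reading of the visual probe, or any
acoustic dependence of the pupil response beyond the condition amplitudes.
Passing tests on synthetic cohorts therefore validate the *pipeline's*
correctness and calibration, not claims about real physiology.

## Numerical choices and problem sizes

* Windows are closed on both ends except the baseline window (closed-open);
  window membership uses a 1e−12 s guard against floating-point drift on
  the sample grid.
* Peak ties break to the first occurrence; events are timestamped at onset.
* The batch path (`preprocess_matrix()`, `matrix_experiment_table()`) is an
  arithmetic-identical vectorization of the per-trial chain (same taps,
  same medians, same interpolation); the test suite asserts equality
  against the per-trial functions to 1e−9. Simulation sweeps — 500 null
  cohorts for type-I calibration and 100 cohorts for effect recovery, each
  35 participants × 112 trials — run through it with shortened traces
  (100 Hz, 0.6 s lead, fixed 1.5 s sentences, a 51-tap filter), a problem
  size chosen so the full calibration remains a desk-scale computation; the
  statistical questions they answer do not depend on trace length.
* The rejection-sampling order generator fails loudly after 10,000 tries
  rather than relaxing constraints.

## Known limitations

* The per-trial MAD outlier rule is aggressive on nearly noise-free
  signals (MAD → 0): this is a property of the published rule, visible only
  in synthetic edge cases; tests that need noise-free fixtures compose the
  filtering and baseline stages directly.
* The split-plot implementation supports exactly two groups (the pooled
  two-experiment design); more groups would need a general mixed ANOVA.
* Audio file I/O (WAV) is out of scope; masker construction operates on
  in-memory waveforms.
* Native eye-tracker formats (ASC/EDF) are not parsed; the readers consume
  the package's delimited text layout.
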