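---
title: "Closed-loop trigger algorithms for movement-paired stimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop trigger algorithms for movement-paired stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vnstrigger)
```

## The problem

Movement-paired vagus nerve stimulation is effective when brief
stimulation bursts coincide with a patient's best rehabilitative
movements, arrive at roughly five per minute, and are separated by at
least five seconds. During supervised therapy a therapist watches the
patient and presses a button; automating that decision requires a
trigger policy that works across patients whose movement amplitudes
differ enormously, across exercises measured in different units
(degrees, grams, touch speed), and within a session as performance
drifts with fatigue or game difficulty.

`vnstrigger` simulates the three candidate policies on single-channel
movement signals and computes the metrics used to compare them. This
vignette is the package's methods reference: the model, every tunable
parameter, the synthetic-data generator, and the numerical choices.

## Signal model and preprocessing

A session is a single channel sampled near 60 Hz with strictly
increasing timestamps. All triggering operates on a *rate-of-change*
signal built causally, as a streaming system would:

1. **Smoothing** — a discrete moving-average (uniform convolution)
   filter over `window_ms = 300` ms of data. The kernel size adapts to
   the sampling rate estimated from the timestamps (median of successive
   differences, robust to dropped samples): `k = round(0.3 * rate)`,
   18 samples at 60 Hz. 300 ms matches the approximate duration of a
   large voluntary movement, long enough to suppress sensor noise
   without erasing movement structure.
2. **Gradient** — central finite differences on the smoothed signal
   (one-sided at the edges), divided by the actual timestamp spacing so
   the result is in signal-units per second regardless of jitter.
3. **Windowed mean** — the gradient is averaged over the trailing
   300 ms, yielding one signed rate-of-change value per sample
   (positive: pressing, gripping, clockwise rotation; negative:
   releasing, counter-clockwise).

Both windows are *trailing only*: no look-ahead, so the offline
simulation reproduces what a real-time implementation would see. For the
first `k - 1` samples a growing window (mean of all samples so far) is
used; this avoids startup discontinuities but means the first few
rate-of-change values are computed from nearly unsmoothed data and are
noisy. Consequences of that transient are handled at the calibration
step (below), not by discarding samples, so sample indices and
timestamps stay aligned throughout.

**Movement minimum.** Each exercise has a noise floor `m`: the mean,
over at-rest recordings, of the maximum absolute rate of change
(`estimate_movement_minimum()`). Samples with |value| at or below `m`
are flagged sub-minimum by `gate_noise()`; they are *flagged, not
removed*, so the rolling buffer's notion of "most recent samples" is
well defined. `calibrate_movement_minimum()` discards the first second
of each preprocessed rest recording before taking the maximum — the
growing-window transient otherwise dominates the estimate by an order of
magnitude (53 vs 4.7 units/s under the default noise level).

## The trigger policies

All three share the inter-stimulus-interval gate: a trigger may fire at
time `t` only if no trigger has fired or `t - t_last >= min_isi`
(default 5 s, measured trigger time to trigger time, with a 1 ns float
tolerance).

**Dynamic (rolling percentile).** A FIFO buffer holds up to
`buffer_size = 3000` of the most recent supra-minimum samples — about a
minute of movement at 60 Hz, long enough to span short game sessions,
short enough to track fatigue and level changes in longer ones. At every
sample the threshold is recomputed as the linearly interpolated
percentile of the buffer (`percentile_threshold()`, the `(n-1)p` order
statistic convention); an incoming supra-minimum value that *strictly*
exceeds it fires a trigger. Strictness matters: a constant signal equals
its own percentile and must never self-trigger. Choices a deployed
system could make either way, and how this package resolves them:

- *Buffer admission*: only supra-minimum samples enter by default, so
  long rests cannot deflate the threshold; `include_subminimum = TRUE`
  admits everything (both behaviours are exercised in the tests).
- *Minimum fill*: the threshold is undefined (and no triggers fire)
  until the buffer holds `min_fill = 30` values — the percentile of a
  near-empty buffer is meaningless.
- *Movement initiation*: no trigger can precede the first supra-minimum
  sample; the flag never reverts within a session.
- *Directionality*: `both` keeps one signed distribution;
  `positive_only`/`negative_only` buffer only samples of that sign
  (negative handled as magnitudes, so "exceeds" is always "greater
  than"); `bidirectional` keeps two independent capacity-3000 buffers
  and two thresholds, for patients whose deficit is worse in one
  movement direction.

The batch runner `run_dynamic()` (C++: a sorted vector paired with the
FIFO, so each step is one binary search plus an ordered insert) is
required by its tests to be exactly equivalent to folding the pure-R
streaming step `dynamic_step()` over the session — two implementations,
one semantics.

**Static (fixed multiple of the noise floor).** Threshold
`multiplier * m`, multiplier in {1, 2, 4, 8, 16, 32}. During a sustained
supra-threshold plateau the algorithm retriggers every `min_isi` seconds
(`retrigger = FALSE` gives the crossings-only variant). A zero movement minimum is rejected — the
threshold would degenerate to zero.

**Periodic (countdown).** Triggers at `start + k * interval`,
k = 1, 2, ..., up to and including the session end; a 60 s session at
the 12 s default yields exactly 5 triggers. The first trigger is one
full interval after start — this is the phase that reproduces the
5-per-minute rate.

## Metrics

- `triggering_rate()`: count / minutes.
- `selectivity_pct_of_max()`: per trigger, |paired value| as a percent
  of the session's maximum |rate of change|; the session value is the
  median across triggers (sessions with no triggers contribute a rate of
  0 but no selectivity value).
- `selectivity_recent_percentile()`: the percentile rank of each
  trigger's paired value inside the buffer snapshot at the trigger
  instant. The rank is the *inverse of the interpolated quantile* (the
  largest rank whose quantile does not exceed the value), so it is
  exactly consistent with the threshold definition: a value strictly
  above the p-th percentile threshold always ranks above p, by
  construction rather than approximately.
- `isi_stats()`: successive trigger-time differences with mean and SEM.
- `periodic_baseline_peak()`: lays a 12 s grid over the session, takes
  the maximum |value| within ±1 s of each grid point, averages over grid
  points, then averages over every grid phase offset stepped at the
  sampling period (the `n_offsets` argument gives the single-phase
  variant). This is the per-session normalisation constant used by
  `percent_improvement_over_baseline()` when comparing policies' paired
  peak sizes.
- `summarize_cohort()`: median, IQR (type-7 quartiles), mean, SEM,
  Tukey whiskers (Q1 − 1.5 IQR, Q3 + 1.5 IQR) and the boxplot-notch
  median interval (±1.58 IQR/√n). `compare_groups()` wraps two-tailed
  paired/unpaired t-tests with explicit guards for zero-variance
  degeneracies.

## The synthetic-session generator

No public dataset of rehabilitation movement streams exists, so
`generate_session()` produces seeded sessions with the statistical
structure the algorithms assume. A session is a sum of raised-cosine
bursts (600 ms full width — a large movement takes roughly 300 ms each
way — giving one clean rate-of-change excursion per direction per
burst), with:

- Poisson burst onsets at `burst_rate = 20`/min (the cadence of
  continuous game-driven exercise), thinned by randomly placed ~15 s
  rest blocks covering `rest_fraction = 0.25` of the session, with the
  candidate rate compensated so the realised count still matches
  `burst_rate`;
- log-normal burst amplitudes, median 30 sensor units with
  `amp_sdlog = 0.3`: a patient's successive repetitions are stereotyped,
  the best only modestly larger than the typical;
- a per-session amplitude scale drawn log-normally with
  `session_scale_sd = 0.6`: patient-to-patient and
  exercise-to-exercise differences are large. This is the single most
  consequential parameter — it is precisely what defeats any fixed
  threshold chosen once for a whole cohort, and removing it makes the
  static policy look spuriously competitive;
- a linear drift envelope (`drift = 0.1`) and additive Gaussian noise
  (`noise_sd = 1.5` raw units, standing in for sensor noise plus
  resting tremor; under the default preprocessing it calibrates to a
  movement minimum near 4.7 units/s);
- for rotation signals, random burst signs with an optional `asymmetry`
  ratio scaling negative-direction amplitudes, to exercise the
  bidirectional mode.

Ground-truth burst annotations (onset, peak time, amplitude, sign) are
returned so tests can attribute triggers to movements without peak
detection. All randomness flows from the config seed, and the caller's
RNG state is restored afterwards.

`simulate_manual_triggers()` models the therapist the dynamic policy is
meant to replace: movement peaks above `detection_fraction_of_max = 0.4`
of the largest movement seen so far are candidates; each is missed with
probability 0.2; the button press lags the peak by a truncated-normal
latency (1.0 ± 0.4 s); presses honour the 5 s gate. The parameters
describe a competent but human observer — rewarding clearly visible
rather than only near-maximal movements, with realistic reaction delay
and divided attention — which reproduces the qualitative finding that
manual triggering beats a periodic timer but not an adaptive percentile.

**What the generator does not emulate**: game-specific signal
idiosyncrasies, multi-channel kinematics, compensation movements,
non-stationary burst shapes, or the amplitude distributions of any
particular clinical population. Passing tests therefore demonstrate the
algorithms' construction-level properties (ISI gating, percentile
selectivity, adaptivity to amplitude scale) on plausible signals — not
clinical performance.

## Numerical choices and degenerate inputs

- Percentile interpolation is linear in the `(n-1)p` convention
  everywhere (threshold, rank, cohort quartiles); the C++ and R paths
  share the arithmetic expression exactly.
- Strict `>` at both thresholds; ISI and periodic end-point comparisons
  carry a 1e-9 s tolerance so sample grids landing exactly on gate
  boundaries are kept.
- Empty signals, fewer than two samples for a gradient, fewer than two
  buffer values for a percentile, zero-variance t-tests, a zero-maximum
  signal in selectivity, and a non-positive baseline all raise immediate
  errors rather than propagating NaN.
- Timestamps are validated strictly increasing at construction and again
  inside the streaming step (out-of-order samples are an error, not a
  reorder).
- Sessions serialise timestamps with 6 decimal places — sub-sample
  precision at 60 Hz; values at full precision.

## Problem sizes

The test suite and the acceptance script run entirely on generated data:
120 s sessions at 60 Hz (7201 samples), cohorts of 100 sessions for the
cohort-level properties, 20 dense sessions for the ISI bound, 50
random streams for the streaming/batch equivalence check, and a
50 000-sample stationary stream for the threshold-exceedance rate check.
The full suite completes in well under a minute on one CPU.

## Known limitations

- The dynamic buffer stores values, not timestamps: at sampling rates
  far from 60 Hz the 3000-sample capacity corresponds to a different
  time span.
- `selectivity_recent_percentile()` requires a dynamic run with recorded
  snapshots; it is not defined for static or periodic triggers.
- The periodic baseline averages over all grid phases at sample
  resolution; for very long sessions the single-phase variant
  (`n_offsets = 1`) is markedly cheaper and usually close.
- Multi-channel fusion (averaging or taking the largest of several
  sensor dimensions) is out of scope.
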