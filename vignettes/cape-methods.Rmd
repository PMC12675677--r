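---
title: "Quality-driven carotid–femoral PWV estimation from multi-channel LDV: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality-driven carotid–femoral PWV estimation from multi-channel LDV: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cape)
```

## Scope and model

`cape` estimates carotid–femoral pulse transit time (PTT) and pulse wave
velocity (PWV) from twelve simultaneously acquired laser-Doppler-vibrometry
(LDV) skin-displacement channels: six over the carotid artery, six over the
femoral artery, nominally sampled at 10 kHz after demodulation. The package
starts from demodulated displacement; demodulation of raw optical IQ
signals is hardware-specific and out of scope.

The timing landmark is the maximum of the displacement signal's second
derivative (the acceleration peak near the foot of the systolic upstroke).
Working on acceleration rather than displacement has two virtues: double
differentiation suppresses low-frequency motion drift (a 0.5 Hz baseline
wander is attenuated by a factor of roughly $(2\pi\,0.5)^2$ relative to the
pulse's sharp upstroke content), and it sharpens the arrival feature that
the pulse wave imprints on the skin.

Per channel, the preprocessing chain is

> low-pass → differentiate → low-pass → differentiate → low-pass,

with a 30 Hz cutoff. Re-filtering after each derivative counters the
high-frequency amplification inherent to differentiation. All filtering is
zero-phase (forward–backward), so no stage delays the landmark.

Fiducial points are detected by template matching. A site-specific 200 ms
acceleration template slides over the channel; at each of the $N$ valid
lags the raw cross-correlation $r[i]$ is computed, and the detection
threshold is

$$\mathrm{CCT} = K \cdot \frac{1}{N}\sum_{i=1}^{N} |r[i]|,$$

with the dimensionless factor $K$ (default 2.5) trading sensitivity for
specificity. Every maximal supra-threshold run of lags yields one fiducial
point. Because both $r$ and the threshold scale linearly with the channel
amplitude, detection with raw correlation is exactly invariant to the
channel's (arbitrary) displacement units — the tests assert this
invariance, and it is why the package never needs calibrated amplitudes.

Detected fiducials are grouped into heartbeats per site and matched across
sites, and all carotid × femoral peak combinations are enumerated — up to
$6 \times 6 = 36$ pair delays per heartbeat. Two quality gates follow:

* **Beat quality threshold (BQT, default 15):** a heartbeat with fewer than
  BQT pairs is discarded (kept if $k \ge \mathrm{BQT}$; the boundary is
  inclusive by design and not configurable).
* **Recording quality threshold (RQT, default 15 per nominal 20 s):** with
  fewer than RQT surviving heartbeats the estimate is withheld entirely and
  the result is graded *unreliable*. RQT is an absolute count; an optional
  `rqt_per_20s` switch scales it proportionally for other durations but is
  off by default.

Per-beat PTT is the median of the beat's pair delays. Four aggregators
combine beats into the overall PTT, named outer-statistic-first:
`mean_mean`, `mean_median`, `median_mean` and `median_median` (default; the
double median is the most robust to outlier pairs and outlier beats, which
the test suite demonstrates against `mean_mean` on contaminated draws).
Finally $\mathrm{PWV} = 0.8\,d/\mathrm{PTT}$, where $d$ is the measured
straight carotid–femoral distance and 0.8 the consensus correction from
straight to effective arterial path length. Estimates are labelled by the
preset the configuration matches — *excellent* (K = 2.5, BQT = 15,
RQT = 15) or *acceptable* (K = 2.5, BQT = 15, RQT = 10) — and *custom*
otherwise; a withheld estimate is always *unreliable*.

The beat-to-beat trend reports each beat's PTT at its beat time; beats
discarded by the gate are filled by linear interpolation between
neighbouring valid beats and flagged `interpolated`, while leading and
trailing gaps remain empty. Slow oscillations of transit time
(respiration, Mayer waves at ~0.1 Hz) therefore remain visible in the
trend without being faked where no data exist.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `cutoff`, `order` | 30, 4 | Hz, – | low-pass; order 4 Butterworth, doubled by the forward–backward pass |
| `K` | 2.5 | – | threshold scale; configured range 1–5 |
| `refractory` | 0.3 | s | min separation of detections on one channel (max ~200 bpm) |
| `peak_fit` | 0.03 | s | half-width of the parabolic peak refinement (0 disables) |
| `beat_gap` | 0.3 | s | single-linkage clustering gap for beats |
| `delay_min`, `delay_max` | 0.02, 0.25 | s | physiological transit window (PWV ≈ 4–20 m/s over typical corrected path lengths) |
| `bqt` | 15 | pairs | local gate, 1–36 |
| `rqt` | 15 | beats | global gate per nominal 20 s |
| `aggregator` | `median_median` | – | outer/inner statistic |

## Numerical choices

* **Filter family.** The 30 Hz low-pass is a 4th-order Butterworth:
  maximally flat over the sub-30 Hz physiological band, standard in
  biosignal work, and free of passband ripple that would distort relative
  peak amplitudes. Forward–backward application squares the magnitude
  response and cancels the phase. The family/order are exposed in
  `filter_spec()` so alternatives can be evaluated.
* **Derivative.** Central differences scaled by the sampling rate, with
  one-sided differences at the endpoints: second-order accurate, zero
  delay, length-preserving. No edge trimming is performed.
* **Cross-correlation.** Raw (unnormalized) valid-overlap correlation,
  computed via FFT with zero padding; the test suite and the acceptance
  script verify equality with a naive two-loop sum to better than 1e-9
  relative error. A per-lag normalized mode exists for experiments with
  morphologically heterogeneous data, but raw correlation is the default
  because the mean-|r| threshold already self-scales.
* **Peak localization.** Within a supra-threshold region the fiducial is
  the local maximum of the *acceleration* signal inside the best-matching
  template window (the landmark is defined on acceleration, not on the
  correlation trace). The discrete argmax is refined by a least-squares
  parabola over ±30 ms — roughly the quarter-period of the ~8 Hz upstroke
  feature, and about two correlation lengths of the 30 Hz-filtered noise —
  which averages noise-induced wander of a flat peak top without biasing a
  symmetric peak. Setting `peak_fit = 0` recovers the plain argmax.
* **Tie-breaks.** Within the refractory period the detection with the
  higher correlation score wins. If one channel contributes two peaks to a
  beat cluster, the higher score is kept (earlier time at equal score). If
  two femoral beats fall inside the transit window of one carotid beat, the
  nearer is matched and the ambiguity is logged; a femoral beat is consumed
  by at most one carotid beat.
* **Degenerate inputs.** Empty delay lists, empty correlation traces,
  too-short signals and epochs, non-positive distances, cutoffs at or above
  Nyquist, and site maps that do not contain both sites all raise classed
  errors (`cape_config_error`, `cape_format_error`, `cape_input_error`).
  An all-zero channel produces no detections because nothing exceeds a
  zero threshold.
* **Boundary semantics.** Gate comparisons are inclusive
  ($k \ge \mathrm{BQT}$, $n_\text{valid} \ge \mathrm{RQT}$). Agreement
  grading uses strict inequalities, so a bias of exactly 0.5 m/s falls to
  the next grade, and the bias is graded in absolute value.

## Open design decisions

Beat segmentation is not prescribed by the estimation model itself, so the
package had to choose one: fiducials from one site are clustered by
single-linkage in time (gap 0.3 s), and each carotid beat is matched to the
femoral beat whose median time lies 20–250 ms after its own. The scheme is
ECG-free, deterministic and order-independent; its parameters sit in
`pairing_config()` precisely so that sensitivity to the choice can be
tested. Pairs whose individual delay leaves the physiological window are
dropped, so the per-beat pair count equals the product of the site peak
counts whenever all combinations are physiological.

Among the four aggregators, two reasonable conventions exist for naming the
mixed forms; here the *outer* statistic over beats is named first
(`median_mean` = median over beats of per-beat mean delays).

## The synthetic generator

Since clinical LDV recordings cannot ship with the package, all testing
rests on `generate_recording()`. It emulates exactly the features the
pipeline consumes:

* a smooth analytic displacement pulse (120 ms raised-cosine upstroke,
  280 ms return) whose filtered second derivative has a single dominant
  sharp maximum — the default detection templates are derived from this
  pulse through the same preprocessing chain as real data;
* beats at a configurable heart rate with Gaussian timing jitter
  (default SD 20 ms);
* a true transit time per beat, `base_ptt` (default 70 ms) plus a slow
  sinusoidal modulation (default ±2 ms at 0.1 Hz, Mayer-wave-like;
  respiratory settings such as ±5 ms at 0.25 Hz are used in the trend
  tests);
* per-channel white Gaussian noise (default SD 0.1 of unit pulse
  amplitude, i.e. 20 dB) added *before* filtering so the pipeline's own
  low-pass shapes it;
* channel dropout, same-site arrival stagger (≤ 2 ms, mimicking the 5 mm
  beam spacing; default 0 — the six same-site channels are treated as
  redundant observers), noise bursts, mistimed replica pulses and baseline
  drift.

Ground truth records every beat's arrival times and transit (the identity
*transit = femoral − carotid arrival* holds exactly) and every channel's
true fiducial instant. Identical seeds give bit-identical recordings.

What the generator does **not** emulate: physiological waveform variety
(reflected waves, inter-subject morphology), amplitude variation across
beats, speckle dropout dynamics, correlated inter-channel noise, and
non-stationary artifact structure. Passing the synthetic suites therefore
demonstrates the correctness and self-consistency of the algorithmic chain
— detection, pairing, gating, aggregation — under controlled conditions,
not clinical accuracy; the agreement module exists precisely so that users
with paired reference measurements can grade the device/pipeline
combination on real data.

The gate-ablation corpus is constructed from the mechanism of each gate:
*beat-corrupted* recordings have, in a majority of beats, all six true
femoral pulses suppressed and two channels carrying a replica pulse
mistimed by +80 ms (such beats produce 12 wrong-delay pairs — enough to
poison an ungated median, few enough for BQT = 15 to discard);
*recording-corrupted* ones have a few beats with mistimed replicas on all
six femoral channels (36 wrong-delay pairs, passing any BQT) and no usable
pairs elsewhere, so only the recording gate can withhold them. The error
dispersion with both gates on is then compared against each ablation.

## Problem sizes

The shipped tests and the acceptance script use 20 s recordings at heart
rate 60 (about 19 beats) for recovery, trend and sweep checks; shorter 4–11 s
recordings for I/O, detection and degradation unit tests; 20 seeded
recordings for parameter recovery; a 10-recording corpus for the ablation
comparison; and 100 random instances up to 10⁴ samples for the
cross-correlation oracle. These sizes were chosen so the full suite
exercises every path at realistic scale while remaining quick to run.

## Known limitations

* Thresholds (K, BQT, RQT and the presets) are operating points adopted
  from guideline-graded practice, not re-derived here; their
  generalizability across populations is an open clinical question.
* Template matching assumes the acceleration morphology resembles the
  template; strongly atypical waveforms may need user-supplied templates
  (`read_template()`).
* The beat matcher assumes at most one heartbeat per `beat_gap` window and
  transit times inside 20–250 ms; severe arrhythmia or extreme PWV would
  require retuning `pairing_config()`.
* The quality gates trade data availability for accuracy: strict presets
  can withhold estimates on noisy recordings by design.
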