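---
title: "Methods: on-device signal processing for a rumen bolus sensor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: on-device signal processing for a rumen bolus sensor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rumenbolus)
```

## Overview

An ingestible rumen bolus monitors a dairy cow for its whole life on a
single battery. Radio energy dominates the budget, so raw sensing (a
3-axis accelerometer at 12.5 or 25 Hz, a temperature probe every few
minutes) must be reduced on the device to one 51-byte packet per hour —
a lossy compression of roughly four orders of magnitude. This package
implements that whole computation at desk scale: the event detectors
that run on the microcontroller, the server-side heart-rate classifier,
the packet codec, the energy arithmetic, and a synthetic-signal
generator that stands in for the animal.

## Drinking detection

Drinking shows up in rumen temperature as an abrupt drop of several
degrees (cold water mixing into ~100 L of rumen content), followed by a
slow recovery. The detector compares consecutive samples: a new sample
more than `th` (default 2 °C) below the previous one is a drinking
event, provided the refractory window `w` (default 2 samples ≙ 10 min)
has elapsed since the last event. Two properties are deliberate:

* The comparison is strictly between *consecutive* samples and the
  reference updates every sample, so a gradual decline — fever
  compensation territory, out of scope here — never trips it.
* `th` below 1 °C is rejected: the temperature sensor's noise floor
  makes such thresholds meaningless.

The reference temperature is initialised to the first sample and
stepping starts at the second, so startup cannot produce a spurious
event.

## Motion activity

Two measures run in parallel on the raw 3-axis stream:

1. **Block peak category.** In non-overlapping 5-min blocks the largest
   per-axis absolute acceleration is binned by 15 ascending thresholds
   into 16 categories (4 bits each). The thresholds default to a linear
   0.5–7.5 G grid and are fully configurable; a vector-norm variant is
   available behind `peak_mode = "norm"`. The peak detector reads the
   raw, gravity-included signal.
2. **Intensity classes.** Gravity is removed by a per-axis exponential
   averager `x̂ ← αx + (1−α)x̂`; the instantaneous intensity is the
   Euclidean distance between the raw and filtered vectors, smoothed by
   a second averager with parameter β, and classified into three classes
   by two thresholds, incrementing a per-class counter each sample.
   Counters reset at each hourly packet and are quantized by a
   saturating right-shift before transmission.

The averager parameters have no published values. Defaults are α = 0.01
(gravity time constant ≈ 8 s at 12.5 Hz: slow enough to pass movement
transients, fast enough to follow the bolus re-orienting in the rumen)
and β = 0.05; both are exposed. The class counters count *samples* —
the per-sample formulation makes the partition property (counters sum
to samples processed) exact; seconds are recoverable via the rate.

## Rumination

Rumination is a regular cycle: a short active chewing burst, then a
longer quiet gap, with a full period of 50–100 s (625–1250 samples at
12.5 Hz). The detector tracks an envelope of the raw intensity —
instant attack, smoothed decay — and applies hysteresis thresholding:
the active state starts when the envelope reaches the high threshold
and ends when it falls to the low one. Full periods are measured
between consecutive active onsets. A period outside the configured
range, or an active part outside its own bounds (default 2–30 s),
interrupts the pattern and empties the FIFO period buffer. When `k = 5`
consecutive periods agree within a relative tolerance of 0.2
(`min/max > 0.8`), rumination is confirmed: the whole buffered time is
credited at once, and each further conforming period adds its own
length.

Design notes:

* The package requires the high threshold to sit at or above the low
  one (hysteresis); the defaults are 6000/3500 on the raw intensity
  scale. An `enforce_hysteresis = FALSE` escape hatch admits an
  inverted pair for experimentation.
* Period length is the positive elapsed time between consecutive
  active-period starts; the first onset only arms the period clock.
* The very first confirmation credits `sum(L)` — time that has already
  passed — so cumulated rumination jumps by five periods at the moment
  of confirmation. This is the intended semantics of a confirm-then-
  backfill counter, and cumulated time can therefore lag or step
  relative to wall-clock truth by up to a few periods at bout edges;
  the 16-min-bout test tolerance (15%) reflects exactly this
  discretisation, not measurement noise.
* Threshold units follow the intensity scale of the input stream. On
  raw sensor LSBs the printed defaults apply; on simulated streams in G
  the thresholds must be chosen on that scale (the tests use 0.25/0.1 G
  against chewing bursts of ~0.6 G).
* Measured period lengths carry a few samples of jitter from the
  envelope's threshold-crossing latency. When the physiological period
  range spans the full 50-100 s acceptance window, a bout cycling near
  100 s can oscillate across the upper bound and be rejected; analyses
  of such streams should widen the period bounds by a small margin
  (the bout-recovery checks use 600-1300 samples). The defaults remain
  the exact 625/1250-sample conversions of 50 and 100 s.

## Heart rate

The heartbeat appears as a small periodic pulse superimposed on
locomotor noise. Per 3-s window (75 samples per axis at 25 Hz):

1. the two axes with the greatest variability (variance after mean
   removal; peak-to-peak and energy variants available) are selected —
   the heart sits close to one sensor axis;
2. each selected buffer is conditioned: moving-mean baseline removal
   (1 s window), zero-phase Butterworth low-pass at 5 Hz, exact mean
   removal;
3. local maxima and minima are sought with a refractory distance of 8
   samples (0.32 s, below the 130-bpm beat spacing) and a relative
   amplitude gate (0.4 of the strongest candidate of the same
   polarity) so noise wiggles between beats cannot split an interval;
4. extremum positions are refined to sub-sample resolution by parabolic
   vertex interpolation — integer positions quantize a median interval
   by half a sample, which is the width of a whole 10-bpm bin at high
   rates;
5. successive differences of the extremum positions give candidate
   inter-beat intervals, and the per-stream *median* is the transmitted
   feature: four numbers per window (maxima/minima on axes A and B),
   each ideally equal to the true inter-beat interval.

Server-side, a single-hidden-layer perceptron (4 inputs in seconds, 16
hidden units, 8 softmax outputs) maps the four features to one of eight
10-bpm categories spanning 50–130 bpm. Bin edges are not published;
equal bins over [50, 130) are the natural reading. Absent features
(fewer than two extrema on a stream) are imputed with the mean of the
present ones; an all-absent window yields no estimate. Training data
come from the simulator: rates drawn uniformly within each bin, windows
passed through the full bolus-side pipeline, and 10% of feature vectors
corrupted by halving or doubling one entry so the network learns to
out-vote a single harmonic confusion. Training is deterministic given
the seed; a stratified 80/20 split reports held-out accuracy before the
final refit on all rows, with weight decay 1e-4 stabilising the
bin-edge boundaries.

On simulated windows sweeping 55–125 bpm (0.02 G pulse, 0.004 G sensor
noise) the end-to-end pipeline recovers the generator's bin in over 90%
of windows; residual errors sit within ~1 bpm of bin edges, where the
3-s window's intrinsic resolution ends. Published error rates on real
animals involve locomotor artifacts far beyond this generator's scope
and are not comparable.

## Telemetry packet

The hourly uplink is exactly 51 bytes — the largest payload the slow
spreading factors allow. Fields are packed big-endian, MSB first:
packet id (u16), temperature (u12, 0.05 °C steps from 30 °C), drinking
counter (u8), three activity class counters (u8), twelve 4-bit peak
categories, rumination (u12, 16 s steps), twelve 4-bit heart-rate codes
(0–7; 15 marks "no estimate"), firmware version, status flags and
battery voltage (u8, 20 mV steps); 27 reserved zero bytes pad to 51.
All quantizations saturate rather than overflow, and decode∘encode is
the identity on the quantized domain. Twelve heart-rate codes mirror
the 5-min block structure of the activity path; the field list is
published but widths are not, so the layout is versioned in
`packet_layout()`.

## Energy budget

With air time `t_tx` (1632 ms at SF12 for 51 bytes) and an hourly
period, the radio duty cycle is `d = t_tx/t_period ≈ 0.45·10⁻³`; the
battery lifetime is `C / (d·i_tx + (1−d)·i_st)` with worst-case
currents `i_tx` = 120 mA and `i_st` = 0.1 mA, giving ≈ 14 years on a
19 Ah cell — radio only, a flat worst-case standby. The compression
ratio is output bytes over input bytes: at 12.5 Hz, 3 axes, 2 bytes per
sample plus six 2-byte temperature readings an hour produces 270,012
input bytes against one 51-byte packet, r_c ≈ 1.9·10⁻⁴. Air times are
taken as given constants rather than derived from an air-time formula.
Note the temperature cadence: the detector path nominally samples every
5 min while the compression arithmetic uses every 10 min (6/h); the
detectors take the interval from the data and the budget object exposes
it as a parameter, so both conventions coexist explicitly.

## The synthetic generator

`sim_config()` + `make_fixture()` produce paired temperature and
acceleration streams with the exact event log used, so every detector
can be scored against ground truth without hardware. What it emulates:

* abrupt drinking drops (default 3 °C) with exponential recovery
  (τ = 1800 s — the functional form is a modelling choice; only "slow
  return" is observable in real traces) and i.i.d. Gaussian sensor
  noise (0.1 °C);
* a fixed-orientation gravity vector of norm 1 G (optionally rotating
  slowly, since the bolus can re-orient), plus white accelerometer
  noise;
* aperiodic Gaussian bursts during general-motion bouts, scaled by an
  intensity class;
* square-wave rumination cycling: a per-bout base period drawn
  uniformly from 50–100 s, each cycle jittered by at most 5% and
  clamped to the range. Independent per-period draws from the full
  range would routinely violate the 20% similarity the detector itself
  requires — real rumination is locally regular, which is precisely
  what the detector exploits, so the generator is locally regular too;
* a biphasic heartbeat pulse (0.3 s, one positive and one negative lobe
  per beat, so maxima and minima both recur once per cycle) weighted
  toward the axes nearest the heart.

Determinism: a configured seed makes every stream bit-identical across
runs, and the generator restores the ambient RNG state afterwards.

What it does *not* model: biomechanics, animal-to-animal variability,
posture, barn environment, sensor drift, or locomotor interference
during heart-rate windows. Passing tests demonstrate algorithmic
correctness against the assumed signal structure, not field performance
on real cattle.

## Problem sizes and numerical choices

The test suite and the reproduction script run everything at the scale
the methods naturally live at: 24 h of 5-min temperature samples for
drinking, single hours at 12.5 Hz (45,000 samples) for activity,
rumination and telemetry, and a few hundred 75-sample windows for heart
rate (480 training, 150 evaluation). Unit identities (averager steps,
fixed points, the 3-4-5 intensity triangle) are asserted to 1e-12;
detector traces are compared exactly against independently written
reference traces; stochastic end-to-end checks use fixed seeds.
Degenerate inputs (empty series, flat windows, inverted thresholds,
wrong payload lengths) raise errors rather than guessing.
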