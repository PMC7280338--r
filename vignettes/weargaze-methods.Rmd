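---
title: "Parsing and analyzing wearable eye-tracker recordings with weargaze"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parsing and analyzing wearable eye-tracker recordings with weargaze}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(weargaze)
```

## The problem

A head-mounted eye tracker records everything as a stream of timestamped
packets: per-eye gaze direction vectors, pupil center and diameter, a
binocular gaze point in scene-camera image coordinates and in 3D, inertial
(gyroscope/accelerometer) samples, TTL input events, and video-frame
timestamps. The stream is line-delimited JSON, gzip-compressed, one file
per *segment* (long recordings are split into several segments by the
device). Nothing in that stream is directly analyzable: packets belonging
to one gaze sample must be grouped, per-eye validity decided, timestamps
regularized, segments concatenated, and all streams expressed on one
clock. `weargaze` implements this pipeline headlessly, along with the
derived kinematic signals, data-quality measures, and an event-annotation
model.

## The packet dialect

One JSON object per line with keys `ts` (integer microseconds on the
recording clock), `s` (status, 0 = valid), `gidx` (gaze-sample group
index, present on gaze-family packets), `eye` (`"left"`/`"right"` on
per-eye packets), and exactly one payload key: `gd` (gaze direction, 3),
`pc` (pupil center, 3), `pd` (pupil diameter, 1), `gp` (2D gaze point,
2), `gp3` (3D gaze point, 3), `gy` (gyroscope, 3), `ac` (accelerometer,
3), `vts` (video timestamp, 1), `sig` (TTL, 1). Unknown payload keys are
skipped and counted; malformed lines are dropped and counted, never
fatal. Each segment directory also carries a small `segment.json`, and
each recording a `recording.json` with names, ids, start time and
calibration status — the fields the recording selector needs. The dialect
is deliberately minimal and fully specified here; packets a real device
emits beyond this vocabulary (battery, API events, ...) are ignored by
design.

## Sample assembly and the validity rule

Packets sharing `gidx` form one gaze sample. An eye counts as **valid**
only when its gaze direction, pupil center and pupil diameter are all
present with status 0 — the minimal generalization of requiring that all
gaze streams be available for a sample. Binocularity follows directly:
both eyes valid → `binocular` (the "green dot" case), one eye →
`monocular_left`/`monocular_right` (the "red dot" case), neither →
`missing`. Invalid eyes expose no angles, so downstream code cannot
accidentally consume bad data. The sample's timestamp is that of its
gaze-direction packet (the earlier one if the two eyes differ).

## Regularization: gaps stay gaps

The nominal rate is inferred as the member of {50, 100} Hz nearest to
`1/median(Δt)`; the median makes this robust to timestamp jitter, and a
deviation beyond 10% of the chosen rate raises a warning. Samples are
then snapped to the exact grid `t0 + k/rate`:

* each sample goes to its **nearest tick**, a tie at exactly half an
  interval going to the earlier tick;
* two samples on one tick keep the earlier, counting a drop;
* unoccupied ticks between the first and last sample are filled with
  samples whose binocularity is `missing`.

No gaze value is ever interpolated: missing data must stay visibly
missing, because gaps themselves are analytically meaningful in wearable
data. After assembly, consecutive timestamps deviate from `1/rate` by
less than a nanosecond, and re-running the regularizer on its own output
is the identity. IMU streams are *not* forced onto the gaze grid; they
keep native timestamps, since they are separate instruments plotted as
separate streams. Segments share one clock by construction, so
overlapping segment time ranges indicate a fault and are fatal rather
than silently re-offset; the span between segments is gap-filled like any
other gap. Video-frame timestamps come from `vts` packets pairing media
time with data time; each segment gets its own piecewise-linear,
end-clamped map (a single pair degenerates to a pure offset), because
media time restarts with each segment's video file.

The assembled recording is cached in `livedata.processed.json.gz`, a
single gzipped-JSON container with the gaze, IMU, TTL and video-map
tables plus metadata and the assembly report. Numbers are serialized with
17 significant digits, so the cache round-trips doubles bit-exactly.

## Orientation and velocity

With the headset frame x right, y up, z forward, gaze direction
decomposes into Fick angles — azimuth about the vertical axis first, then
elevation: `θ = atan2(x, z)`, `φ = asin(y)`, both in degrees, which makes
the decomposition unique with `|φ| ≤ 90°`. The frame and sign conventions
(θ positive rightward, φ positive upward) are this package's convention;
the synthetic generator uses the same one, keeping every oracle internally
consistent.

Velocities use a Savitzky–Golay differentiation filter: a least-squares
polynomial of order `p` (default 2) fit over a centered window of `w`
samples (default `2·round(0.05·rate)+1`, about 100 ms — a common choice
for saccade-scale smoothing), whose derivative at the center is the
velocity estimate. The window is a user-facing setting because it trades
noise suppression against attenuation of fast events. Two numerical
choices matter:

* **Edges and gaps produce no output.** A window containing any missing
  sample, or truncated by the series edge, yields a non-finite velocity.
  Shrinking the window near gaps would silently change the filter
  bandwidth mid-recording.
* **Attenuation is real and quantified.** The order-2 derivative filter's
  coefficients coincide with the order-1 filter's on a symmetric window,
  and its response attenuates a sinusoid of frequency `f` by a factor
  `Σ c_j sin(2πf j Δt) / (2πf)`. At 100 Hz with an 11-tap window this is
  a 1.17% underestimate of a 1-Hz component's derivative — measurable in
  the tests, and the reason analyses of noise-free synthetic data use a
  3-tap window. Order 3 reduces the attenuation below 0.01% at the cost
  of noise amplification.

Eye speed combines the axis velocities as
`ω̇ = sqrt(θ̇² cos²φ + φ̇²)`, computed per eye (binocular averaging is
left to callers, since per-eye traces are what the validity model
produces naturally).

## Data quality

Two measures, chosen to be comparable across recordings made with the
same setup:

* **RMS-S2S** per eye and per axis: the RMS of successive-sample
  differences within a 300-ms moving window (stride one sample — the
  densest, parameter-free choice), median over windows. Windows containing
  any missing sample are excluded entirely so every retained window rests
  on the same number of differences. The median estimates precision during
  slow-movement periods without explicit fixation masking: windows
  containing saccades or artifacts are a minority, so a single 1000 °/s
  spike moves the estimate by well under 1%. For iid Gaussian noise of
  standard deviation σ the statistic concentrates near `σ√2`, a couple of
  percent below it (the median of a windowed chi statistic), which the
  tests account for by simulating the estimator itself.
* **Data loss**: the percentage of regularized samples with binocularity
  `missing`; gap-filled samples count as lost, since they represent time
  the tracker delivered nothing.

## Event streams

An event stream is a named, contiguous series of non-overlapping labeled
intervals `[start, end)` with optional per-label flags (e.g. a `vergence`
flag on saccades). Manual streams may leave uncoded spans; classifier
output must cover the whole timeline. Editing follows timeline-click
semantics: a new annotation runs from the end of the latest annotation
ending at or before the clicked time (or from zero) to the click; splits
duplicate label and flags; boundaries drag within their neighboring
edges. TTL activity becomes a locked stream either as `edges` (one
annotation per event, widened to one gaze interval so `end > start`
holds) or `levels` (held value until the next change). Text-file streams
(`start_s`, `end_s`, `label`, `flags` TSV) stay editable but remember
their file contents, and reset restores exactly the loaded annotations —
re-serialization is byte-identical. All codings persist in an open
`coding.json` beside the recording, so external tools (e.g. a
manual-mapping coder) can append streams that appear on reload.

### Classifiers

Classifiers are plugins: a registered function receives the full recording
plus a named parameter list (each parameter with value, range, and a
user-settable flag, validated before every run) and returns an event
stream. The built-in `slow_fast` classifier thresholds the smoothed eye
speed (binocular mean where both eyes are finite, otherwise the finite
eye; default 100 °/s) and then merges runs shorter than a minimum duration
(defaults 10 ms fast, 40 ms slow) into a neighboring phase — shortest run
first, into the longer neighbor, ties to the earlier one; missing spans
never merge. It is a deliberately simple, fully documented
velocity-threshold algorithm honoring the plugin contract;
domain-specific algorithms from the literature can be registered alongside
it. Identical recording and parameters always yield identical streams.

## The synthetic generator

`generate_recording()` renders a scripted scanpath into the exact packet
dialect, with ground truth returned for oracle comparisons. Saccades use
a minimum-jerk displacement profile because its peak velocity has the
closed form `1.875 · amplitude / duration` — an oracle convenience, not a
claim about real saccade dynamics. Fixations add iid Gaussian noise per
eye and axis (default 0.1°, a realistic precision for this class of
device; anisotropic `c(azimuth, elevation)` values are supported); gaps
delete gaze packets while the IMU keeps running; monocular episodes drop
one eye's packets to exercise the red-dot path; TTL pulses and a
segment-split time emulate button presses and the device's splitting of
long recordings. Identical script and seed produce a byte-identical tree
(gzip with zeroed modification time).

What the generator does **not** emulate: timestamp drift between streams,
pupil dynamics beyond constant-plus-noise, saccade kinematics of real
eyes (main-sequence curvature, glissades), blink artifacts with partial
validity patterns, or vendor-specific auxiliary packets. Tests passing on
synthetic data therefore demonstrate the pipeline's correctness —
grouping, validity, gridding, kinematics, quality arithmetic,
classification mechanics — not the behavioral validity of any classifier
on real recordings, which always needs inspection against real data.

## Problem sizes and defaults

The test-suite and acceptance computations run at desk scale: recordings
of 5–120 s at 50 or 100 Hz (up to ~6000 gaze samples), 10⁴ randomized
annotation edits, and a handful of Monte-Carlo replicates for the RMS-S2S
oracle — sizes at which every check completes in seconds while still
exercising multi-segment, gap, and jitter paths. Key defaults: quality
window 300 ms; SG window ≈100 ms, order 2; classifier threshold 100 °/s
with 10/40 ms minimum durations — all overridable through the JSON
configuration (`inst/config/defaults.json`), which rejects unknown keys
with their location.

## Known limitations

* Rate inference only considers 50 and 100 Hz nominal rates.
* No head-motion compensation: eye velocity is eye-in-head; gyroscope
  fusion is out of scope.
* No accuracy (offset) estimation — precision and loss only.
* Scene/eye video decoding, gaze overlay and any interactive display are
  out of scope; video is represented only by its timestamp maps.
* The slow/fast classifier is a velocity threshold with duration merging;
  it does not implement adaptive-threshold algorithms from the
  literature, though they can be plugged in.
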