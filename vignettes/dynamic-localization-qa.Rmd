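---
title: "Dynamic localization QA for SGRT: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic localization QA for SGRT: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgrtdynqa)
```

## The QA problem

Surface-guided radiotherapy (SGRT) systems report the 6-DoF offset of a
monitored surface region — lateral/longitudinal/vertical translations and
yaw/pitch/roll rotations — relative to a reference capture, in real time.
For intra-fraction motion monitoring during stereotactic treatments the
system must report *small, dynamic* displacements accurately, which is
what a monthly dynamic localization test probes: drive a rigid phantom
through known couch motions and compare what each independent data source
says the couch did against what it was commanded to do.

Three sources are compared:

* **trajectory log** — the linac's own record of expected and actual axis
  values plus cumulative MU, on a uniform grid (50 Hz here);
* **surface log** — the SGRT stream of 6-DoF surface offsets, at its own
  (generally lower, here 15 Hz) and possibly irregular rate, with no
  beam-on flag;
* **MV images** — radiographic truth for translations via a single
  implanted bb. Rotations cannot be resolved from a single bb, so MV
  verdicts are structurally absent (not zero) for rotation steps.

Verdicts use the AAPM TG-142 SABR tolerances: 1 mm for translations,
1 degree for rotations, boundary inclusive (a deviation of exactly the
tolerance passes — the conservative QA reading that avoids flagging a
measurement that sits on the limit).

## The motion plan

`build_motion_plan()` encodes the monthly sequence: translation offsets
{−50, −10, +10, +50} mm on the lateral and longitudinal axes at gantry 0,
the same set vertically at gantry 90 (the detector views the lat/lng
plane at gantry 0 and the vrt/lng plane at gantry 90), and rotation
sweeps of ±3° in 0.5° increments on yaw, pitch, and roll. Design
decisions worth stating explicitly:

* **Step deltas are absolute offsets from the reference pose.** The
  couch returns through zero between axes and the plan ends with an
  explicit home step, so the cumulative pose after the final step equals
  the reference exactly. Within an axis the sweep is monotone with zero
  skipped — the simplest deterministic reading.
* **One axis moves per step**, which is what makes a single-axis
  expected-vs-measured comparison well defined.
* **Rotation steps deliver a beam-on dwell (50 MU) but acquire no MV
  image.** A single-bb phantom cannot resolve rotations radiographically;
  the dwell exists because every position summary in the analysis is an
  average *over beam-on time*, and rotation positions need such a window
  too.
* **Delta-zero reference images** are acquired at each gantry angle used
  for translations; radiographic offsets are differences against the
  reference detection at the same gantry angle, which cancels any static
  detector/collimator offset.

The XML control script (`render_developer_xml()`) uses a self-defined,
versioned schema — one `<controlPoint>` per step carrying absolute axis
values — because the proprietary vendor scripting schema is not
published. Documents round-trip byte-identically through
`parse_developer_xml()`.

## Log dialects

Real linac trajectory logs are vendor-binary; this package defines open
CSV dialects (`trajlog` v1, `surflog` v1: a `# key: value` header block,
then one row per sample) as its interchange format, and treats conversion
from proprietary formats as out of scope. Values are written with six
decimals, so file round-trips are exact to 1e-6 in the units of each
column. The surface dialect deliberately has no beam-on column; if one
appears it is ignored with a warning, mirroring the fact that the
monitored stream itself carries no such flag.

## Synchronization and averaging

The two logs need not share a clock. Alignment follows the
first-instance-of-motion rule:

* **Baseline**: per-axis mean over the first 1 s of each log (the
  simulator idles 1.5 s before any motion, so the baseline window is
  clean by construction; with clinical logs the operator should likewise
  start recording before the script runs).
* **Onset**: the earliest sample starting a run of `min_run = 5`
  consecutive samples on which one axis deviates from its baseline by
  more than 0.1 mm / 0.1°. The thresholds sit above the sensor noise
  (0.05 mm 1-sigma by default) and below the smallest planned motion
  (0.5° / 10 mm). The run-length requirement matters: with a threshold
  at 2 sigma of the noise, a bare first-exceedance rule false-triggers
  with high probability somewhere in the pre-motion window, while a
  sustained step is still reported at exactly its first sample. Raising
  the threshold can never produce an earlier onset.
* **Resampling**: the surface series is shifted by (surface onset −
  trajectory onset) and linearly interpolated onto the trajectory grid,
  clamped at the edges. Linear interpolation is the least-assuming
  choice for a piecewise-ramp motion profile.

Beam-on windows are maximal runs of per-sample MU increments above
`mu_epsilon = 1e-3` MU; window bounds span the ramp so the delivered MU
per window reconstructs the planned 50 MU to numerical precision. Poses
are averaged arithmetically inside each window; rotation axes use a
wrap-safe mean, which coincides with the plain mean for the ±3° motions
of this plan.

**Latency.** `estimate_time_lag()` reports the onset shift plus the
residual lag maximizing the normalized cross-correlation of the
translation traces. Because onset alignment itself absorbs the true
latency, the residual alone is near zero by construction; only the total
is meaningful, and it is reported as informational — never a pass/fail
criterion. With a 15 Hz surface stream the onset shift alone is
quantized to ~67 ms, so the cross-correlation refinement is what brings
recovery inside one trajectory sample period (20 ms).

## MV image analysis

The bb is radio-opaque: a dark disc of projected diameter
`bb_diameter_mm × SID/SAD` (5 mm × 1.5 = 7.5 mm = 22.32 px at 0.336 mm
pitch) on the bright open field. Detection is deterministic:

1. invert about the image median (background subtraction);
2. matched-filter with the projected-disc template
   (`EBImage::filter2`, replicate boundary) and take the peak, excluding
   a border margin;
3. reject unless the peak's robust z-score (vs. the median/MAD of the
   filtered field) is at least 8 *and* the local patch correlates with
   the template at 0.5 or better — a uniform or bb-free image must raise
   a detection-failed error so QA flags it rather than guessing;
4. iterated intensity-weighted centroid over a circular mask of radius
   R + 3 px around the peak (3 recentering iterations).

The mask radius is a bias/variance compromise: it must cover the full
soft edge of the blob (bias) while bounding the noise lever arm
(variance). A plain threshold-centroid detector is included as a
cross-check only.

Pixel displacements against the same-gantry reference detection convert
to isocenter millimetres by Δx = Δp · pitch · SAD/SID (defaults SAD
1000 mm, SID 1500 mm, pitch 0.336 mm; metadata in the image sidecar
takes precedence). The detector orientation convention (+column = +lat
at gantry 0 / +vrt at gantry 90; +row = +lng) is fixed here and
validated end-to-end against the simulator's ground truth.

## The simulator: what it emulates, and what it does not

`simulate_session()` generates the three data streams from a plan with
known ground truth:

* **Couch motion**: constant-speed ramps (20 mm/s, 3 deg/s; gantry
  6 deg/s) between poses, a 0.3 s quiet gap, then a stationary dwell
  (2 s) during which MU ramps linearly. The quiet gap models beam
  ramp-up after motion stops; it also guarantees that the surface-onset
  quantization error (up to one 15 Hz sample) cannot leak moving-couch
  samples into a beam-on averaging window — without it, zero-noise
  closure at the millidegree/micron level is impossible.
* **Surface**: the phantom is rigid, so the true surface offset equals
  the couch offset (an optional per-axis scale factor models a
  miscalibrated system for negative-control tests), delayed by the
  configured latency and sampled at the surface rate with independent
  Gaussian noise per axis per sample (defaults 0.05 mm / 0.05 deg
  1-sigma).
* **Images**: the bb renders as a radially symmetric disc with a logistic
  edge (softness 0.5 px), modelling source/detector blur. The soft edge
  is also a numerical choice: the intensity-weighted centroid of a
  sampled hard-edged disc is biased by up to ~7e-3 px depending on the
  sub-pixel phase, while the logistic edge keeps the bias below ~6e-4 px,
  which is what lets a zero-noise session close to 1e-3 mm through the
  radiographic chain.
* **Determinism**: a single seed fixes every draw; identical (plan,
  config, seed) triples are bit-reproducible.

What the simulator does *not* model — and what passing tests therefore do
not demonstrate about a clinical system: trajectory-log actual-vs-expected
machine error (actual equals expected exactly), MV scatter and detector
distortion, deformable or partially occluded surfaces, camera-pod optics,
and the noise spectrum of a real SGRT stream (the 15 Hz rate and white
Gaussian noise are placeholders; vendors do not publish either). The
simulator verifies the *analysis*, not the hardware.

## Numerical choices and degenerate inputs

* Angles normalize to (−180, 180]; all planned rotations are far from the
  wrap, and the wrap-safe mean only engages if samples straddle it.
* XML numbers print at full double precision (`%.17g`), log files at six
  decimals, report JSON at 17 significant digits — each format's
  round-trip tolerance is stated with it.
* Empty plans render to a valid document with an empty sequence; empty
  logs write header-only files; a single-sample surface log cannot be
  interpolated and errors; an interval containing no session samples
  errors naming the interval; an empty record set refuses report
  generation.
* Beam-on interval counts must match the plan's beam-delivering step
  count exactly; a mismatch is a consistency error rather than a silent
  re-indexing.

## Problem sizes used in validation

The test-suite study conditions are the defaults above. The heavier
checks run: 200 seeded noisy sessions (0.05 mm / 0.05 deg, 0.20 s
latency) for parameter-recovery statistics — per-position surface-mean
errors standardized by sigma/sqrt(n) against N(0, 1) (n being the native
surface samples in the window, since interpolation correlates the
resampled 50 Hz points), and latency recovery within one trajectory
sample period in at least 95% of sessions; 500 synthetic images at
SNR 10 for detection accuracy (median error ≤ 0.1 px) plus 100 bb-free
images for rejection; and ~100 randomized instances per round-trip
format. `scripts/acceptance.R` re-runs the same measurements at 100
sessions / 200 images.

## Known limitations

* Rotations are never verified radiographically (single bb); a multi-bb
  or wire phantom would be needed.
* Onset-based alignment makes the absolute latency estimate partly
  self-referential; a beam-on flag in future surface-log versions would
  allow alignment at beam-on and a clean latency measurement.
* DICOM MV images are not read directly; convert to 16-bit TIFF/PNG with
  a JSON geometry sidecar upstream.
* The trajectory-log dialect is an open stand-in; decoding vendor binary
  logs is out of scope.
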