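# sgrtdynqa

Automated monthly quality assurance of the **dynamic localization
accuracy** of surface-guided radiotherapy (SGRT) systems.

SGRT systems monitor a patient's surface in real time during treatment and
must report small displacements accurately — both in magnitude and in
time — for intra-fraction motion monitoring during stereotactic
(SRS/SABR) deliveries. AAPM TG-302 recommends a monthly dynamic
localization test, but no vendor procedure exists for it. The workflow
implemented here automates the test end to end: a scripted couch drives a
rigid head phantom (with an implanted 5 mm radio-opaque ball bearing,
"bb") through known translations and rotations; couch motion is then
verified independently from three sources and judged against the AAPM
TG-142 SABR tolerances of **1 mm and 1 degree**:

1. the linac **trajectory log** (expected/actual couch axes + cumulative MU),
2. the SGRT **surface log** (6-DoF surface offsets from a reference capture),
3. **MV portal images** of the bb taken after each translation.

This package is aimed at clinical medical physicists and QA-software
developers. It builds the motion plan and its XML control script, parses
the logs (open CSV dialects), synchronizes the two time series by first
motion, averages poses over beam-on time at each couch position, detects
the bb with sub-pixel accuracy and demagnifies pixel offsets to isocenter
millimetres, and emits a tolerance-checked QA report. A built-in
simulator generates complete sessions with known ground truth, so the
whole pipeline is testable without a linac.

## Method sketch

* **Motion plan** — lateral and longitudinal couch offsets of ±10 and
  ±50 mm at gantry 0°, the same offsets vertically at gantry 90°, then
  yaw/pitch/roll sweeps of ±3° in 0.5° increments (zero skipped). An MV
  image and 50 MU are delivered at every translation position; rotation
  positions get a beam-on dwell so that every position can be averaged
  over beam-on time.
* **Synchronization** — the surface log carries no beam-on flag, so the
  two series are aligned at the first instance of motion; the surface
  series is linearly interpolated onto the trajectory grid. Total
  latency is estimated as the onset shift plus the residual lag that
  maximizes the normalized cross-correlation of the translation traces.
* **Beam-on averaging** — beam-on windows are segmented from the
  cumulative MU channel (per-sample increment > ε); couch-actual and
  surface poses are averaged inside each window.
* **bb detection** — background-subtracted matched filtering with a
  projected-disc template, then an iterated intensity-weighted centroid.
  Pixel displacements Δp map to isocenter millimetres via the
  divergent-beam relation Δx = Δp · pitch · SAD/SID.
* **Report** — per-step signed deviations (measured − expected) per
  source, the signed maximum of largest magnitude per source, and
  pass/fail verdicts at the TG-142 SABR tolerances (boundary inclusive).

## Worked example

```r
library(sgrtdynqa)

plan <- build_motion_plan()                # 52 control points
cfg  <- simulation_config(seed = 3, surf_latency_s = 0.2)
ses  <- simulate_session(plan, cfg)        # logs + 14 MV images
res  <- run_dynamic_qa(plan, ses$trajectory, ses$surface, ses$images)
print(res)
```

```
<qa_report> overall: pass
  traj: pass
  surf: pass
  mv: pass
  50 position summaries, 12 MV offsets, latency 0.193 s
```

With the default 0.05 mm / 0.05 deg surface noise, the report's
per-source maxima (signed, largest magnitude) come out well inside
tolerance, e.g.:

```
| source | kind        | max deviation | n  |
|--------|-------------|---------------|----|
| traj   | translation | +0.000        | 12 |
| surf   | translation | +0.016        | 12 |
| mv     | translation | +0.008        | 12 |
```

The estimated latency (0.193 s here, for an injected 0.20 s) is reported
as informational only: with onset-based alignment it reflects the
alignment itself, never a pass/fail criterion.

The same workflow is available from the shell:

```sh
Rscript inst/cli/sgrt-dynqa.R plan     --out plan.xml
Rscript inst/cli/sgrt-dynqa.R simulate --plan plan.xml --out session/ --seed 3 --latency 0.2
Rscript inst/cli/sgrt-dynqa.R analyze  --plan plan.xml --session session/ --out report/
```

`analyze` accepts any session directory holding `trajlog.csv`,
`surflog.csv`, and `images/` (16-bit TIFF/PNG with JSON geometry
sidecars) — simulated or assembled from clinical exports.

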