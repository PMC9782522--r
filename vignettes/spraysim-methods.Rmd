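---
title: "How spraysim models a vision-guided spot sprayer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How spraysim models a vision-guided spot sprayer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spraysim)
```

## The system being simulated

`spraysim` is a desk-scale simulator of one *scalable unit* of a modular
precision sprayer: a downward-looking camera streams frames over a
broadcast-seeded crop row, a single-shot detector labels weeds and crop
plants with bounding boxes, and a solenoid valve opens for a fixed burst
whenever a scheduled weed passes under the nozzle. Because the crop is
broadcast seeded there are no inter-row lanes, so every spraying decision
must come from per-plant detection. The simulator reproduces the control
law of such a unit — tracking, vision-based speed estimation, spray
scheduling, footprint-based schedule clearing — against a synthetic ground
truth, so that targeting and volume metrics can be computed exactly.

The package deliberately models no imagery. The detector is emulated at
the level of its *output statistics* (per-class miss rate,
misclassification, clutter, box jitter, confidence distributions), which
is the level at which the control law consumes it.

## Synthetic fields

A row is a `length x width` rectangle (default 10 m x 0.5 m). Plants are
placed by a homogeneous Poisson process: counts per species are
`Poisson(density x area)` and positions are uniform. The replica
configuration uses weed densities 6.6, 17.8 and 11.8 weeds/m² on three
adjacent rows and a crop density of 39.5 plants/m² (the 395,000 seeds/ha
sowing rate at full emergence; an `emergence` fraction is available). With
`exact_counts = TRUE` the counts are the rounded expectations — 33, 89 and
59 weeds — matching the fixed populations of the field trials the
simulator emulates.

Canopy radii are lognormal with median 0.04 m. They are synthetic: the
trials report no plant sizes, and the radius only sets bounding-box extent
and has no effect on scheduling beyond pixel-centre location.

Thirty target weeds and thirty non-target soybeans are sampled uniformly
across the rows, mirroring the trial protocol. A sampled soybean is
"without adjacent weeds" iff no weed lies within `adjacency_radius` of it.
The trials never quantify "adjacent"; the default 0.15 m is on the scale
of the per-row footprint half-width and is configurable. Adjacency is
computed in across-row global coordinates, so a weed just over a row
boundary still counts as adjacent.

## Camera and detector emulation

The camera images a fixed ground window centred on the sprayer frame,
1280 x 720 px at 19 frames/s (the effective inference rate of the vision
hardware being modelled). The machine's specification table does not print
the field of view; the default window of 0.95 m (along travel) x 0.53 m is
calibrated so that `window length x fps = 18.05 m/s`, the quoted maximum
operating speed of the vision module — at that speed consecutive frames
tile the ground exactly. `gap_check()` tests this condition for any
speed/camera pair.

Projection is exact and sub-pixel: a plant whose centre is inside the
window produces a box at `(ground offset from the trailing window
edge) / gsd`, clipped to the frame. Pixel x runs along the travel
direction, so plants drift toward pixel 0 as the sprayer advances.

`corrupt()` applies the noise chain per frame: independent per-species
miss (default 0.32, i.e. the 68% per-frame recall operating point of the
detector being emulated), misclassification (default 0), centre jitter
(sd 3 px), multiplicative size jitter (sd 5%), and Poisson clutter
(0.2 boxes/frame, uniform position, size resampled from true boxes).
Confidences are Beta(8,2) for true boxes and Beta(2,4) for clutter; the
control loop thresholds at 0.5, so a small tail of true boxes is lost
there and most clutter is rejected. These defaults are the simulator's
study conditions, not tuning knobs: they are either stated operating
points of the emulated detector or, where nothing is stated, fixed
realistic choices documented here.

What the emulator does *not* reproduce: occlusion and canopy overlap
(misses are independent across plants and frames), growth stages,
correlated detector failures on small plants, motion blur, and terrain-
induced camera pose changes. Consequences for interpreting results are
discussed under Limitations.

## Tracking and speed estimation

Boxes are associated between consecutive frames by greedy nearest-
neighbour matching on centre distance, same species only, with a gate
(default 120 px, about twice the per-frame displacement at the fastest
recorded speed). The field system's description does not name an
association method; greedy matching is chosen for its `O(n²)` simplicity,
and an exhaustive minimum-distance assignment is available behind
`method = "optimal"` for cross-checks. On unambiguous frames the two
coincide, which the test suite verifies by enumeration.

Each match contributes a speed `-dx_px * gsd / dt` (plants move backward
in the frame as the sprayer advances). The frame estimate is the median
over matches — robust to a single wild mis-association — and the reported
estimate is the rolling median of the last `k = 5` frame estimates. With
no matches the previous value is held and flagged invalid, and no
schedules are created from that frame. Both weed and soybean tracks feed
the estimate by default; a crop-only restriction can be emulated by
filtering the stream, but is not the default because the emulated
detector treats both classes symmetrically.

On noiseless constant-speed streams the estimate is exact to floating
point, because box centres are kept sub-pixel; the 2% recovery tolerance
used in the tests therefore exercises the whole loop rather than a
quantization artefact.

## Spray scheduling

The nozzle trails the camera frame centre by `offset` (default 0.30 m;
the machine's drawings show the separation but print no value, and no
result below depends on it). For a weed whose box centre sits `rel`
metres ahead of the frame centre, the remaining travel is
`d = offset + rel` and the trigger time is `t_now + d / v_est`. Weeds
with `d <= 0` have already passed the nozzle and are dropped. Schedules
are appended every frame a weed is seen, so one weed normally queues
several near-identical triggers.

A poll runs once per frame (the real controller polls "regularly" at an
unstated rate; the frame period is the natural choice here). If any
pending trigger has elapsed, the earliest fires one spray event — a
late-elapsed job fires immediately rather than being dropped — and the
valve is considered open for `t_spraying = 0.2` s.

One actuation wets a stretched-ellipse patch of width `2 h tan(θT)` and
length `t_spraying v + 2 h tan(θL)`; with the 0.45 m nozzle height and
1.08 m pattern width this is 1.08 m x 1.218 m at 0.69 m/s. Footprints are
georeferenced at the nozzle position at fire time, using the speed
estimate at fire time (not schedule time). The hit test uses the
bounding rectangle by default — conservative and simple — with the
ellipse (stadium) shape behind a flag.

Two mechanisms suppress redundant sprays:

* **Clearing.** After the sprayed-feedback signal, every still-pending
  job whose target falls inside the fired footprint's along-travel
  interval is cleared. The published description restricts clearing to
  the x-interval of "the effective spray region of the previous
  spraying"; a 2-D variant exists behind a flag for logs that record a
  cross-track target.
* **Coverage guard.** New schedules are suppressed for targets inside
  the most recent fired footprint. Clearing alone cannot prevent double
  sprays: a weed wetted by the leading half of a footprint is still
  visible in later frames and would re-enter the queue. The guard is the
  schedule-side counterpart of the same feedback filter and is what makes
  the no-double-actuation property hold exactly in noiseless runs. It can
  be disabled (`guard_covered = FALSE`) to study the unguarded behaviour.

A consequence of footprint-based clearing is that valve counts in the
simulator are governed by footprint length (fires are spaced at least
half a footprint apart), which is well below the theoretical ceiling
`ceil(L / (t_spraying v))` — 73 for a 10 m row at 0.69 m/s — and below
the actuation counts reported from the field, where the effective wetted
area per actuation is evidently narrower than the nominal pattern. Valve
counts and spray volumes reported by the simulator are therefore its own
figures for its own footprint model.

## Metrics

Sampled plants are scored against fired footprints: sprayed sample weeds
are TP, unsprayed sample weeds FN, sprayed sample soybeans FP, unsprayed
sample soybeans TN. The metric suite is, in percent:

* spraying precision `Ps = 100 TP / (TP + FP)`
* spraying recall `Rs = 100 TP / (TP + FN)`
* wrong-spraying rate `WS = 100 FP / (TN + FP)`
* non-targeting rate `NT = 100 TN / Ns|wow`, where `Ns|wow` counts the
  sampled soybeans with no adjacent weed.

Zero denominators yield `NA` (undefined), never 0. Values are kept
unrounded and formatted to two decimals only at presentation.

Volume accounting: `Q_variable = N_valve x (Q_nozzle / 60) x t_spraying`
(the delivery rate is quoted in L/min while the opening time is in
seconds, so the unit conversion is explicit in the code),
`Q_uniform = n_rows x (Q_nozzle / 60) x t_trial`, and
`SVR = 100 (Q_uniform − Q_variable) / Q_uniform`. SVR is 100% with no
actuations, strictly decreasing in the actuation count, and negative when
actuations exceed the continuous-spray equivalent.

Multi-trial reports print both the metrics of the averaged counts and the
mean of per-trial metrics; the two differ in general (ratios of means are
not means of ratios) and the field-trial tables are ambiguous about which
was used, so neither is privileged.

Detection quality is scored with PASCAL VOC 2007 conventions: greedy
confidence-ordered matching at IOU 0.5, each truth matched once, 11-point
interpolated AP per class, mAP the unweighted class mean. The all-point
AP is available behind a flag. A class with no ground truth gets an
undefined AP rather than 0.

## Numerical and design choices

* Box coordinates are floating-point pixels; nothing is rounded to the
  pixel grid. This keeps noiseless runs exact and makes quantization
  bounds in the tests meaningful.
* One master seed is split into per-purpose sub-seeds (field, sampling,
  per-trial noise and trajectory) so changing one setting never
  reshuffles the others; all library functions restore the caller's RNG
  state.
* Greedy association breaks ties by scan order of the distance matrix;
  fixtures in the tests are constructed to be tie-free.
* The trial trajectory draws an independent speed per frame from
  0.53–0.83 m/s (the recorded rough-terrain range around the 0.69 m/s
  average). Trial duration is set so the nozzle clears the row end plus
  half a static footprint at the slowest speed.
* Replay integrates estimated speed for position (a log carries no ground
  truth), so replayed event *times*, valve counts and clearing decisions
  reproduce the original run exactly, while georeferenced centres agree
  only up to the integrated estimate.

## Problem sizes

The shipped tests and the acceptance script run three trials over three
10 m rows (181 weeds, ~590 soybeans, about 420 frames per row per trial),
plus property checks on 1000-seed count calibration and 20–25 randomized
oracle fixtures. These sizes make every stochastic check stable at fixed
seeds while keeping a full run in the tens of seconds on one core; they
are stated here so results are read at the scale they were computed.

## Limitations

* Rs = 100% in the replica conditions shows that multi-frame redundancy
  (a weed is seen in ~26 consecutive frames at 0.69 m/s, so a 32% miss
  rate leaves a per-weed miss probability around `0.32^26`) makes the
  scheduler robust to the emulated noise. It does not show robustness to
  *correlated* misses — a small occluded weed missed in every frame —
  which the independence assumption cannot represent.
* FP/TN-type figures (Ps, WS, NT) depend strongly on the footprint hit
  test and the synthetic plant layout; with the nominal 1.08 m pattern
  width nearly every sampled soybean near a spray is counted as wetted,
  which is more pessimistic than visual field scoring of actual wetting.
  These figures are comparable between simulator configurations, not with
  field reports.
* One nozzle per unit; multi-nozzle targeting, droplet/drift physics and
  wind are out of scope (the modelled machine centres the nozzle in a
  shrouded frame, so wind is ignored there too).
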