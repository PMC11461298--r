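---
title: "Characterizing action-observation video stimuli: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing action-observation video stimuli}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stimchar)
```

## The problem

Event-related analyses of action observation assume that the event of
interest — the agent starting to move, or the action's category becoming
recognizable — happens at a known latency after the trigger. In raw video
stimuli neither is true: clips carry variable stretches of still frames
before motion, and the kinematic or goal character of an action only becomes
discernible partway through. A 3-frame spread at 60 Hz is already 50 ms of
jitter (`frames_to_seconds(3, 60)`), enough to smear early evoked
components. `stimchar` measures both latencies per video and edits clips so
that motion always begins at frame 2.

## Motion onset by frame differencing

### Model and assumptions

The detector assumes a *static* camera and background and a *single* moving
agent. Frame 1 is taken as the background reference and never updated: there
is no running-average background model, because stimulus clips begin with a
deliberate still period and adaptive backgrounds would absorb slow motion
onsets. Every subsequent frame is converted to grayscale and compared
pixelwise to the reference.

### Parameters

* `threshold_fraction` (default **0.10**, dimensionless): fraction of the
  8-bit intensity range a pixel must change by to count as different. The
  comparison is inclusive, `|Δ| ≥ 0.10 × 255 = 25.5`, so the smallest
  integer change that registers is 26 levels. Ties count as changed.
* `min_box_area` (default **400 px**): changed pixels are grouped into
  8-connected regions and each region is summarized by its bounding box;
  boxes with `w × h` below this floor are discarded. This is the main noise
  filter — sensor flicker, fabric wrinkles and small shadows produce
  compact change regions well under 400 px, while a moving person at
  stimulus resolution produces far larger ones.
* `roi_y` (default: full frame height): an inclusive vertical band; a box
  must overlap it to count. Only Y is restricted, since an actor's
  horizontal position varies across clips while the vertical band they
  occupy is stable. The band is a per-database calibration with no
  universal value, hence the permissive default.

The area test uses the *bounding box* area, not the filled contour area:
the box is what downstream cropping and inspection tools consume, and for
the compact blobs the filter must reject the two are nearly identical.
Connectivity is 8-connected so that a diagonally moving edge is one region,
not a staircase of fragments (the labeling is EBImage's 4-connected
`bwlabel` plus a union-find merge of diagonally touching labels; tests
check it against an independent flood-fill).

### Trimming and human override

The onset frame is the first frame with a surviving box; `trim_to_onset()`
keeps frames `onset − 1 …` end, so the onset lands on frame 2 and frame 1
is again a valid static reference. Re-detection on a trimmed clip yields
onset 2 whenever the motion persists at its onset frame — this
detect → trim → re-detect loop is the package's own verification step, and
is exercised over randomized synthetic clips in the test suite. Where a
human frame-by-frame judgment disagrees with the detector,
`resolve_onsets()` applies the human judgment and reports the disagreement;
the detector's known failure modes (shadows, eye movements) are handled by
this override rather than by modeling.

## The recognition staircase

One staircase iteration is one naive participant: they watch the clip up to
`played_frame`, the clip pauses, and they classify the action. The first
participant sees up to the 50th percentile of frames (rounded half-up).
After a correct classification the next participant sees N frames fewer;
after an error, N frames more, with

\[ N = \frac{N_{frame}}{2} \cdot 2^{-(n-2)/2.5}, \]

evaluated at the *destination* iteration \(n\). Taken at face value this
makes the first adjustment (into iteration 2) equal to \(N_{frame}/2\), so
the second participant always sits at a clamped extreme (frame 1 after a
correct first answer, \(N_{frame}\) after an error). We implement the
formula as printed rather than soften it: the subsequent geometric decay
(halving every 2.5 iterations) walks the sequence back from the extreme,
and parameter recovery is unaffected.

Numerical choices, each covered by a test:

* N stays **real-valued** for the stopping test (`convergence_iteration()`
  returns the first n with N < 1; N = 1 exactly has *not* converged) but is
  **rounded half-up** to whole frames when applied — only whole frames can
  be played. Rounding half-down would differ only at exact .5 ties and
  nothing in the procedure distinguishes the two; half-up matches the
  package-wide rounding convention.
* Played frames are clamped to `[1, Nframe]`.
* The schedule length depends only on `Nframe`, never on responses: 21
  iterations for 300-360-frame clips, 18 for 128. `run_staircase()` takes
  an `n_iterations` override for labs that stop earlier by convention.
* The frame played at the final iteration is the convergence frame; no
  update follows the last response.

### What recovery can and cannot achieve

With a deterministic threshold observer (correct iff `played ≥ r`) the
procedure recovers r to within **1 frame** across the whole r grid at
`Nframe = 300` — the bound was established with an independent brute-force
simulation over every r and is frozen in the tests as a regression bound.
With a *stochastic* observer (guessing at 1/3 below threshold, 5% lapses
above) a single staircase run is far less precise: an early lucky guess
moves the sequence by a large step that later small steps cannot undo. The
acceptance script measures this directly
(`staircase_stochastic_median_abs_err`, the median |convergence − r| over
500 seeded runs); single-run medians land near 8-12 frames, an order of
magnitude above the deterministic bound. This is a property of the
procedure, not of the implementation — the independent oracle gives the
same numbers — and is worth knowing when interpreting convergence frames
from a single between-subject chain of real participants.

## Psychometrics

`fleiss_kappa()` is the standard fixed-rater-count formulation:
\(P_i = (\sum_j n_{ij}^2 - n)/(n(n-1))\), \(p_j = \sum_i n_{ij}/(Nn)\),
\(\kappa = (\bar P - \bar P_e)/(1-\bar P_e)\) with \(\bar P_e = \sum_j p_j^2\).
When every rating falls in one category \(\bar P_e = 1\) and κ is undefined;
the result is flagged rather than thrown, so batch evaluations of degenerate
simulated tables survive. `one_sample_t()` implements the closed-form t, CI
and one-sample Cohen's d \((\bar x - \mu_0)/s\), and exposes a
summary-statistics mode so published (mean, SD, n) triples can be checked
without raw data; the raw-data path is cross-checked against `stats::t.test`
in the tests. Accuracy works in counts and percentages simultaneously
(they must satisfy `pct × n_items / 100 = count`, a tested invariant), and
the t test is scale-consistent either way, so both entry points are exposed.
Repeated-measures ANOVA and post-hoc machinery is deliberately out of
scope: `write_ratings()` emits tidy long-format CSV that any stats package
consumes directly.

## Synthetic data: what it does and does not emulate

`make_motion_video()` builds clips with the statistical structure the
detector assumes: a static background (flat or with a static Gaussian
texture, quantized to 8-bit), one rectangular "actor" patch of configurable
area and intensity step that appears or drifts from a known onset frame
inside a configurable actor band, and optional distractor events — small
flashing squares that model the detector's real-world false-positive
sources (shadows, flicker) as sub-area or sub-threshold changes. Defaults
sit at the study's conditions where they exist (60 fps; onsets in frames
2-18 are the regime the tests span; patch area 900 px ≥ the 400 px floor;
intensity step 120 ≫ the 25.5-level cutoff) and at desk scale where only
runtime is at stake (200 × 200 px frames, 24-40-frame clips; the generator
itself is resolution-free and a 3-6 s, 720 × 1280 clip is expressible).

What the generator does **not** emulate: articulated human kinematics,
photometric shading, camera noise correlated in time, or compression
artifacts. Passing the recovery suites therefore shows that the detector's
logic (thresholding, component grouping, area/ROI filtering, first-hit
reporting) is exact under its own assumptions — it does not certify
performance on natural video, which is precisely why the human-override
path exists. All generators are pure functions of `(spec, seed)`: identical
inputs give bit-identical outputs, and neither generation nor observer
simulation touches the global RNG stream.

Test and acceptance problem sizes — 51 onset-recovery clips at 200 × 200,
200 random ≤ 64 × 64 oracle masks, 500 stochastic staircase replicates, 200
null-κ replicates of 200 items × 10 raters — were chosen so the full suite
runs in well under five minutes on one CPU while keeping Monte-Carlo error
small against the margins being tested.

## Known limitations

* Video I/O is lossless PNG frame directories only; compressed containers
  must be exploded to frames upstream. This keeps threshold behavior exact
  and matches the frame-by-frame workflow, at the cost of disk space.
* The detector has no shadow or illumination model; systematic lighting
  changes will register as motion. Use the actor band, the area floor and
  the human override.
* Fleiss' κ is reported without a bootstrap CI.
* A single stochastic staircase chain has limited precision (see above);
  where precision matters, run multiple seeded chains and aggregate.
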