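---
title: "Quantifying neutrophil reverse migration from cell tracks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying neutrophil reverse migration from cell tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmtrack)
```

## The problem

In sterile-injury models of inflammation, neutrophils transmigrate out of a
vessel lumen, chemotax through the matrix toward the injury (here modeled as
a circular spheroid region), dwell there, and — for a subpopulation — leave
again. That last behavior, *reverse migration* (rM), matters because it is
one route by which inflammation resolves instead of festering. Live imaging
of microphysiological injury devices yields per-cell track tables (track id,
frame, x, y in pixels); `rmtrack` turns those tables into the standard
reverse-migration readouts:

1. spheroid-centered coordinates,
2. per-step distances and velocities,
3. a three-segment partition of each track (approach / within / reverse),
4. an rM label per cell,
5. per-segment track straightness `str = disp / d_total`,
6. cell-location heatmaps by 2D Gaussian KDE with Scott's-rule bandwidths.

## The model and its conventions

**Units.** All coordinates are converted to micrometers at ingest
(`read_tracks(..., pixel_size = )`) and all times to minutes
(`frame_interval`); every downstream statistic is in µm and min. Neither
quantity has a default — they are properties of the acquisition and are
never guessed. Frames are 0-based and the first frame is at time 0.

**Alignment.** Coordinates are translated so the spheroid center sits at
the origin: `x_new = x - x_sp`, `y_new = y - y_sp`. A translation changes
no distance, velocity, or straightness value (the test suite asserts this
to 1e-12); it only makes the radial contact test read directly off the
coordinates.

**Contact and segmentation.** A cell is *in contact* at slice *i* when
`sqrt(x_i^2 + y_i^2) <= radius`, boundary inclusive. Contact is evaluated
on recorded positions only — a chord that crosses the disk between two
outside positions does not count, because the data are the recorded
positions. With `F` the set of contact indices, the track partitions into
*approach* (indices before `min(F)`), *within* (`min(F)` through `max(F)`
inclusive), and *reverse* (after `max(F)`). The reverse segment is anchored
at the **last** exit: a cell that pops briefly outside the radius
mid-dwell and re-enters has that excursion absorbed into *within*, since
by definition the reverse phase is never followed by re-entry. A track
whose first point is already inside the radius simply has an empty
approach segment; nothing in the contact rule requires an approach phase.

**The rM label.** A cell is labeled reverse-migrated when it (a) contacted
the spheroid, (b) has a reverse segment of at least 2 points (a single
post-exit point is not evidence of migration *away*), and (c) its final
position lies at least `min_reverse_displacement` µm beyond the radius.
The default threshold is 0 — the pure contact-based definition. The
positive-threshold variant operationalizes the stricter reading under
which a cell must have "travelled away for a minimum distance"; the two
definitions are not reconciled in the literature this implements, so the
threshold is a user-facing parameter rather than a hidden choice.

**Straightness.** For each segment with at least 2 points,
`d_total` is the sum of consecutive point-to-point distances, `disp` the
straight-line distance from the segment's first to last point, and
`str = disp / d_total` (1 = perfectly straight). On a segment where the
cell never moved (`d_total = 0`) both `str = 0` and `str = 1` would be
defensible, so `str` is reported as `NA` and left to the analyst.

**Velocity.** The reported per-segment `mean_velocity` is the mean of
per-step velocities (`velocity_method = "step_mean"`). When a tracker
misses detections and consecutive rows are `g` frames apart, the step's
time is `g * frame_interval`: the chord is spread over the true elapsed
time rather than inventing positions. The alternative convention —
segment distance over segment duration (`velocity_method = "segment"`) —
is exposed because published "average velocity" figures rarely say which
was used; the two agree exactly on gap-free tracks.

**KDE.** The location heatmap evaluates
`f(g) = (1/n) * sum_i K_hx(gx - x_i) * K_hy(gy - y_i)` with Gaussian
kernels and per-dimension Scott bandwidths
`h_j = sigma_j * n^(-1/(2+4)) = sigma_j * n^(-1/6)`, `sigma_j` the sample
standard deviation with the conventional `n - 1` denominator. This is the
diagonal form of Scott's rule — the minimal 2D extension of the scalar-`h`
kernel formula; the full-covariance variant is deliberately not
implemented. The default grid is the data bounding box padded by 3
bandwidths at 128 × 128 nodes, which keeps the Riemann integral of the
density within 1% of 1 (asserted in tests with 5-bandwidth padding). By
default all track points are pooled; `density_points = "final"` restricts
to final positions, since either pooling is found in published heatmaps.

## The synthetic-track generator

No public tracking dataset accompanies the study design this package
serves, so `simulate_trackset()` generates ground-truth-labeled cohorts
that emulate the device geometry: each cell starts on the lumen line at
`x = center_x - lumen_offset`, `y` jittered around `center_y`
(`lumen_jitter_sd`, default 50 µm — about half the spheroid radius, so
approach angles vary without cells starting behind the spheroid), and
performs a biased persistent random walk:

* **speed** per step is drawn from a normal distribution truncated at 0
  (default mean 4 µm/min, sd 1 — inside the 3–5 µm/min range typical of
  neutrophil interstitial chemotaxis in microphysiological systems),
  damped by `within_speed_factor` (default 0.5) while inside the radius,
  matching the observed slowdown at the injury site;
* **heading** is the persistence-weighted circular mean of the previous
  heading and the current target direction (spheroid center during
  approach; the reverse direction during reverse) plus Gaussian angular
  noise (`heading_noise_sd`, default 0.3 rad);
* on first contact the cell **dwells** for a geometrically distributed
  number of frames (memoryless — the minimal assumption given that dwell
  times are not characterized), moving without directional bias;
* after the dwell it reverse-migrates with probability `p_rm` (target:
  back toward the lumen, or a random direction under
  `rm_mode = "random"`), else it keeps moving without bias **inside** the
  spheroid.

Cells that stay at the injury site are *retained*: a dwell-phase step that
would cross the boundary is folded back by radial reflection. This is a
deliberate modeling choice — the non-rM phenotype is, by observation, the
cell that remains at the injury site, and without retention a long
unbiased walk would carry every non-reverser out of the radius eventually,
making "did this cell reverse-migrate" ill-defined even in the generator's
own ground truth. Consequently only cells that switch to reverse mode ever
leave, entry/exit frames are well-defined, and classifier accuracy against
ground truth is a meaningful 0–100% scale.

Determinism: each track is generated from a substream derived from
`(seed, cell index)`, so the same parameters give bit-identical output and
enlarging `n_cells` appends tracks without reshuffling existing ones.

**What the generator does not emulate** — and hence what passing tests do
*not* demonstrate about real data: no chemokine field or gradient decay
(the approach bias is geometric, not mechanistic), no endothelium or
transmigration mechanics, no cell–cell interactions or swarming, no
z-dimension, no tracking errors (missed detections, identity swaps) unless
you introduce frame gaps yourself, and dwell/persistence parameters are
chosen for testability, not fitted to measurements (none are published at
this resolution). Classifier validation on these cohorts shows the
*implementation* recovers known labels under clean geometry; it does not
estimate real-data error rates.

## Numerical choices

* Simulated defaults: 120 frames at 2 min/frame (a 4 h imaging window),
  spheroid radius 100 µm, lumen 300 µm away. Test cohorts use 100–500
  cells; the classifier-recovery checks use 150 frames and mean dwell 5
  so every reverse phase has room to clear 2 radii.
* Straightness on noiseless simulated approaches equals 1 to 1e-12
  (collinear steps accumulate no rounding beyond that).
* `disp <= d_total` is asserted with relative slack 1e-12 (triangle
  inequality up to floating point).
* The truncated-normal speed draw uses rejection sampling; at sd = 0 it
  returns the mean exactly, which is what makes the noiseless limit exact.
* Mann-Whitney comparisons always use the normal approximation
  (`exact = FALSE`): segment metrics are continuous, but identical or
  heavily tied groups would otherwise trigger method switching mid-report.
* Ties in none of the segment rules need breaking: boundary equality is
  contact (`<=`), and `min`/`max` of the contact set are unambiguous.

## Worked example

```{r example, eval = FALSE}
library(rmtrack)

cfg <- pipeline_config(
  out_dir = "run1",
  sim = simulation_params(n_cells = 200, n_frames = 150,
                          dwell_frames_mean = 5, p_rm = 0.3, seed = 42),
  min_reverse_displacement = 50)
res <- run_pipeline(cfg)
res$summary$n_rm                 # reverse-migrated cells found
res$summary$segments$within$velocity  # slower inside the injury site

# real data instead:
ts <- read_tracks("tracks.csv",
                  dialect = track_dialect("Track", "Slice", "X", "Y"),
                  pixel_size = 0.65, frame_interval = 2)
m <- cohort_segment_metrics(ts, spheroid = spheroid_geometry(512, 480, 150))
```

## Known limitations

* 2D only; projecting 3D motion onto the imaging plane biases distances
  downward, as with any planar tracking analysis.
* Contact is point-based; a fast cell could in principle cross the disk
  between frames undetected. At 3–5 µm/min and 2 min/frame steps are
  ~6–10 µm against a 100 µm radius, so this is negligible at realistic
  frame rates but would not be at very long intervals.
* The KDE has no boundary correction; density leaks across the spheroid
  edge and the lumen wall.
* Single-point tracks are preserved at I/O and flagged by
  `validate_trackset()`, but contribute to no kinematic statistic.
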