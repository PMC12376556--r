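# rmtrack

Quantifies **neutrophil reverse migration (rM)** from 2D cell-track tables,
as produced by manual or automatic trackers imaging a microphysiological
sterile-injury model: cells leave a vessel lumen, chemotax toward a
circular injury spheroid, dwell there, and a subpopulation migrates away
again. `rmtrack` is for experimentalists who have track tables
(`track id, frame, x, y`) plus the injury geometry and want the standard
rM readouts without re-deriving them per study.

## What it computes

With the spheroid center at the origin (`x_new = x − x_sp`,
`y_new = y − y_sp`), a cell is in contact at slice *i* when

```
sqrt(x_i^2 + y_i^2) <= radius
```

Each track splits into three contiguous segments: **approach** (before
first contact), **within** (first through last contact — brief boundary
excursions in between are absorbed, since the reverse phase is defined
from the *last* exit with no re-entry), and **reverse** (after the last
exit). A cell is labeled rM when it contacted the spheroid, has a
reverse segment of ≥ 2 points, and ends at least
`min_reverse_displacement` µm beyond the radius (default 0).

Per segment the package reports the path length `d_total = Σ dist_i`
(with `dist_i` the inter-frame Euclidean distance), the displacement
`disp` (first to last point), the **track straightness**

```
str = disp / d_total        (1 = perfectly straight)
```

and the mean velocity in µm/min. Cell-location heatmaps use a 2D
Gaussian KDE with per-dimension Scott's-rule bandwidths
`h_j = σ_j · n^(−1/6)`.

Because such tracking data is rarely public, `simulate_trackset()`
generates ground-truth-labeled cohorts (biased persistent random walk:
directed approach at ~4 µm/min, slow unbiased dwell, reverse exit with
probability `p_rm`) so every stage is testable end to end.

## Worked example

```r
library(rmtrack)

cfg <- pipeline_config(
  out_dir = "run1",
  sim = simulation_params(n_cells = 200, n_frames = 150,
                          dwell_frames_mean = 5, p_rm = 0.3, seed = 42),
  min_reverse_displacement = 50)
res <- run_pipeline(cfg)
```

writes `tracks.csv`, `truth.json`, `metrics.csv`, `labels.json`,
`density.csv`, `summary.json`, and `run.log` into `run1/`. The summary for
this configuration reports:

```
n_cells 200   n_contacted 200   n_rm 53
approach velocity 3.96 ± 0.014 µm/min   straightness 0.947
within   velocity 1.95 ± 0.011 µm/min
reverse  velocity 4.02 ± 0.012 µm/min   straightness 0.944
Mann-Whitney approach vs within velocity: W 40000, p 4.8e-67 (***)
classifier accuracy vs ground truth: 1
```

i.e. 53/200 cells reverse-migrated (p_rm = 0.3 among contacting cells,
here all 200 contacted), cells crawl at half speed inside the injury site
(`within_speed_factor = 0.5`), forward and reverse migration are equally
straight, and the radius-contact classifier recovers every simulated
label. The per-cell table looks like:

```
   cell_id  segment n_steps     d_total       disp       str mean_velocity   rm
1 cell_001 approach      28  211.934597 199.304203 0.9404043      3.784546 TRUE
2 cell_001   within       1    3.923426   3.923426 1.0000000      1.961713 TRUE
3 cell_001  reverse     118  958.728733 915.049020 0.9544400      4.062410 TRUE
4 cell_001    whole     149 1188.502931 720.302421 0.6060586      3.988265 TRUE
```

For real tracker exports, skip the simulator:

```r
ts <- read_tracks("tracks.csv",
                  dialect = track_dialect("Track", "Slice", "X", "Y"),
                  pixel_size = 0.65,      # µm per pixel
                  frame_interval = 2)     # min per frame
metrics <- cohort_segment_metrics(ts, spheroid = spheroid_geometry(512, 480, 150))
labels  <- classify_reverse_migrated(ts, spheroid_geometry(512, 480, 150))
heat    <- kde_heatmap(align_to_spheroid(ts)$points)
plot(heat, spheroid = spheroid_geometry(0, 0, 150))
```

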