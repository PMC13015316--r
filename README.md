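# protrudyn

Protrusion-resolved analysis of amoeboid cell migration from fluorescence
time-lapse movies.

Fast-migrating cells such as neutrophils move by extending transient,
high-curvature membrane protrusions (pseudopods) at the leading edge while a
myosin-II-rich rear retracts. Understanding how cortical non-muscle myosin II
(NMII) engagement at the front and rear coordinates these events requires
measurements at the resolution of individual protrusions, not whole-cell
averages. `protrudyn` provides that pipeline for cell biologists and image
analysts working with calibrated multi-channel time-lapse stacks — plus a
synthetic amoeboid-cell movie generator with scripted ground truth, so every
stage of the pipeline is verifiable without any imaging data.

## What it computes

For each segmented, tracked cell the pipeline derives:

- a **100-point subpixel boundary** per frame (Otsu segmentation,
  minimum-displacement centroid tracking, level-set contour + active-contour
  refinement, even arc-length resampling, stable cyclic anchoring);
- **per-point kinematics**: signed boundary motion, signed local area change
  `a_k` (hexagon shoelace areas that tile the swept region, so
  `Σ_k a_k = ΔArea`), and curvature `κ_k` from windowed Pratt circle fits
  (11 points), signed positive on outward bulges;
- **cortical NMII levels** in 100 sections of a 2 µm cortical shell,
  normalized per cell as
  `I_k(t) = (I_raw,k(t) − I_raw,min) / (I_raw,mean(t) − I_raw,min)`
  (minimum pinned to 0, cell mean to 1, invariant under gain/offset), with
  voxel-weighted smoothing over sections `k−2 … k+1` and a
  front (30) / rear (30) / sides (20+20) partition driven by the migration
  direction;
- **protrusion events**: maximal runs with `κ > 0.2 µm⁻¹`, 5-point centres,
  birth by non-overlap with the previous frame, lifetimes ending at
  retraction onset, transient / stable (> 6 s) / long-life (> 30 s) classes,
  expansion and disassembly rates, per-event NMII level and localization
  lifetime;
- **migration and coordination statistics**: speeds, tortuosity `l/|s|`,
  direction autocorrelation `Corr(Δt) = ⟨n(t)·n(t+Δt)⟩`, lagged Pearson
  correlations of front-protrusion vs rear-retraction activity with
  percentile-bootstrap CIs and a peak-validity criterion (lower 95% CI
  > 0.2), zero-centered curvature–intensity correlations, and
  threshold-persistence curves `F(x_thr, t_thr)` with per-threshold ANOVA;
- **directionality states**: z-scored directional parameters (ND, TPL, STA,
  PR, ANGVAR, TI, TP15–TP85, speed) of globally aligned protrusion windows,
  SVD PCA with a sign-anchored PC1, the composite directionality index
  `CDI = mean(z)`, a median split into high/low states, and
  transition-probability / run-length statistics of each cell's state
  sequence.

## Worked example

Simulate one migrating cell with two scripted protrusions and run the
boundary-dynamics and protrusion analyses on the generator's own boundary
and intensity tables (no rendering or segmentation needed for this route):

```r
library(protrudyn)

p <- simulation_params(n_frames = 30, centroid_speed = 0.1,
                       direction_persistence = 0.95, seed = 1)
p$protrusion_schedule <- random_protrusion_schedule(p, n_events = 3, seed = 101)
cell <- simulate_cell(p)

dyn <- analyze_boundary_series(cell$boundaries, p$frame_interval,
                               I_raw = cell$section_intensity,
                               N = cell$section_voxels,
                               I_raw_mean = cell$cell_mean_intensity)
events <- detect_protrusions(dyn$kappa, dyn$trackings, dyn$area, p$frame_interval)
events$events[, c("Frame", "lifetime_s", "class", "expansion_rate")]
#>   Frame lifetime_s  class expansion_rate
#> 1     4         12 stable      0.2240050
#> 2    13         30 stable      0.3019799
```

The two detections match the scripted ground truth exactly: events born at
frames 4 and 13 with expansion+stabilization durations of 6+6 = 12 s and
12+18 = 30 s (a protrusion's lifetime ends at retraction onset, so it equals
E+S). Expansion rates are in µm²/s of the 5-point protrusion centre.

```r
pm <- path_metrics(dyn$centroids, p$frame_interval)
sprintf("avg speed %.3f um/s, tortuosity %.2f", pm$avg_speed, pm$tortuosity)
#> "avg speed 0.101 um/s, tortuosity 1.22"

ft <- dyn$frame_table
colMeans(ft[c("I_front", "I_rear", "I_side")], na.rm = TRUE)
#>  I_front  I_rear  I_side
#>     2.09    3.08    0.07
```

The recovered speed matches the scripted 0.1 µm/s, and the normalized
region levels reproduce the generator's cortical polarity: a strong rear
pool, a weaker fluctuating front pool, quiet sides.

For the full image route, render the movie and run
`analyze_timelapse(render_movie(cell))`, which segments, tracks, extracts
boundaries, builds cortical sections and returns the same `cell_dynamics`
object computed from pixels. Movies round-trip to disk via
`write_timelapse()` / `read_timelapse()` (multi-page TIFF plus a YAML
metadata sidecar), and a thin CLI for the generator lives at
`inst/cli/protrudyn-simulate.R`.

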