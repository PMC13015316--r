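---
title: "Protrusion-resolved boundary and cortical dynamics of migrating cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Protrusion-resolved boundary and cortical dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protrudyn)
```

## The analysis in one paragraph

Amoeboid cells such as neutrophils migrate by repeatedly extending transient
membrane protrusions (pseudopods) at the leading edge while the contractile
rear retracts. `protrudyn` turns segmented fluorescence time-lapse movies of
such cells into protrusion-resolved measurements: a 100-point subpixel
boundary per frame; per-point boundary motion, signed local area change and
curvature; normalized cortical myosin II (NMII) intensity in 100 cortical
sections partitioned into front, rear and two sides; detection, tracking and
classification of high-curvature protrusions; lagged correlations between
front protrusion and rear retraction activity; and a PCA-based composite
directionality index (CDI) that stratifies protrusions into high- and
low-directionality states whose temporal organization is summarized by
first-order transition probabilities and run lengths.

## Boundary machinery

**Segmentation and tracking.** Each frame of the cell-marker channel is
thresholded with a single global Otsu value over the 3D volume; connected
components below a configurable voxel count are dropped, and objects are
linked frame to frame by the minimum-displacement criterion applied to their
geometric centroids (exact assignment enumeration for small object counts,
greedy nearest-pair beyond, capped by a maximum linking distance). Cells
tracked for at least 10 frames with average speed (path length over elapsed
time) of at least 0.1 µm/s are *motile*; slower active cells are *jiggling*;
non-activated round objects, which in the original workflow were sorted
manually, are marked *still* through an explicit curation flag — a
rule-based surrogate that keeps the analysis reproducible.

**Boundary extraction.** The object's max-projection is traced at the
segmentation threshold with subpixel linear interpolation, refined by a
classic active contour (elasticity `alpha`, rigidity `beta`, and an
edge-attraction force from the gradient of the smoothed image; 15 iterations
by default — enough to regularize pixel-level jaggedness without the
shrinkage bias that long snake runs introduce), oriented counterclockwise,
and resampled to exactly 100 evenly spaced points. Point 1 is anchored to
the previous frame's point 1 by nearest-point correspondence (first frame:
at the heading angle), which keeps the cyclic indexing stable for point
tracking.

**Kinematics.** Point tracking between consecutive frames is the
order-preserving cyclic shift minimizing total squared displacement; motion
is signed positive where the point leaves the previous polygon (protrusion)
and negative where it moves inside (retraction). The local area change at a
point is the area of the hexagon built from the point in both frames and the
midpoints to its neighbours in both frames. Because adjacent hexagons share
edges, their signed areas tile the swept region: we therefore take the sign
from the hexagon's orientation (outward sweep positive), which coincides
with the motion sign in all non-degenerate cases and makes the per-point
areas sum to the exact total area change; self-intersecting hexagons fall
back to the absolute shoelace value with the motion's sign and are flagged.
Curvature at each point is the inverse radius of a Pratt algebraic circle
fit over the point and five neighbours per side, signed positive where the
boundary is locally convex (bulging outward), so protrusions carry positive
curvature.

**Cortical sections and normalization.** The cortical shell is 2 µm deep:
the inner contour is the boundary offset inward along the normals, clamped
at the medial axis (via the distance transform) where the cell is thinner
than the shell. Every projected cell pixel falling into a section
quadrilateral contributes its z-column of cell voxels to that section
(ties to the nearest section centre); pixels in no section form the
unassigned interior, so section voxel counts plus the unassigned count
conserve the cell's total voxel count. Raw section means are normalized per
cell as `I_k(t) = (I_raw,k(t) − I_raw,min) / (I_raw,mean(t) − I_raw,min)`,
where `I_raw,min` is the minimum over all sections and all frames of the
track and `I_raw,mean(t)` averages *all* cell voxels (not just cortical
ones — the alternative reading would rescale `I_k` but change nothing
qualitative; the all-voxel reading matches the measurement's description).
This pins the global minimum to exactly 0, maps a section at the cell mean
to exactly 1, and makes `I_k` invariant under affine rescaling of the raw
intensities (gain/offset), so detector settings cancel. The smoothed
per-point level `I'_k` is the voxel-count-weighted average over sections
k−2 … k+1 (cyclic). That asymmetric four-section window is deliberate: the
formula defining the measurement uses exactly these indices, and we treat
the formula as authoritative over the accompanying description of "two on
each side"; a symmetric five-section variant (`window = "symmetric"`) is
provided for comparison.

**Regions.** The rear is the 30-point arc centred on the boundary point
whose outward direction is most anti-parallel to the migration direction
(the unit displacement over the next two frames, undefined at the last two
frames of a track); the front is the antipodal 30-point arc; the remaining
40 points split into two 20-point sides. Front and rear widths are the
spans perpendicular to the migration direction. Region levels are
voxel-weighted means of the unsmoothed `I_k`.

## Protrusion detection and classification

A protrusion region at a frame is a maximal cyclic run of boundary points
with curvature above 0.2 µm⁻¹; its centre is the highest-curvature point
with two points of half-width on each side (five points). A *new*
protrusion is born when this centre, mapped through the point tracking,
does not overlap any qualifying run in the previous frame. The centre is
then tracked forward; the centre rate is the summed local area change over
the five centre points. The protrusion "keeps protruding or staying" while
that rate is non-negative; its lifetime runs from birth through the
retraction-onset frame (the first frame with negative rate), a convention
chosen so that a protrusion scripted to expand for E seconds and stabilize
for S seconds has lifetime exactly E+S. Classes follow the printed cuts:
transient (≤ 6 s), stable (> 6 s), long-life (> 30 s, a subset of stable).
The expansion rate is the mean positive centre rate before the steady stage;
the steady-stage onset is the first frame whose rate falls below a fraction
ε of the event's peak rate, with ε = 0.1 by default — the source text
truncates mid-sentence exactly where this cutoff would be stated, so ε is a
documented surrogate recorded in the output metadata. The disassembly rate
is the mean (negative) centre rate after the lifetime ends. Events still
alive at the end of the movie are right-censored, flagged, and excluded
from rate statistics. Protrusion NMII engagement uses the same window
convention as the smoothing (indices k−2 … k+1 around the centre): the mean
level over the lifetime, and the localization lifetime as the longest
consecutive run above a threshold (1.1 is the high-intensity preset).

## Correlation and persistence statistics

Offset Pearson correlations align x(t) with y(t+Δt) on their overlap;
percentile bootstrap 95% confidence intervals resample time points of the
aligned overlap with replacement (B = 1000 by default, seeded). The
resampling unit and B are not stated in the source methods; independent
resampling of time points is the plain reading, and a stationary block
bootstrap (geometric block lengths) is available because activity series
are autocorrelated. The peak-correlation offset is reported as a
characteristic time difference only when the lower CI limit at the peak
exceeds 0.2; positive offsets mean the rear lags the front. Front
protrusion and rear retraction magnitudes are the summed positive front
area changes and summed absolute negative rear area changes per frame —
the source names these totals without a formula, and this is the direct
reading. Zero-centered correlations replace the x-mean by 0 in the
covariance (`Cov'(x,y) = <x(y−<y>)>`, normalized by `sqrt(<xx> Cov(y,y))`)
so that the sign of curvature or motion, not its deviation from the mean,
drives the association with intensity.

Threshold-persistence curves summarize fluctuating single-cell series
without choosing a characteristic level: for each threshold, the fraction
of frames a cell stays above it (f), then per experiment the fraction of
cells with f above t_thr (0.5 by default, 0.67 as the variant), averaged
over experiments with SEM, compared across populations by a one-way ANOVA
at every threshold (no multiple-testing correction by default, matching
the original analysis; `stats::aov` does the arithmetic). F(x_thr) is
non-increasing by construction.

## Directionality states

Each completed protrusion defines a half-open global-frame window
`[Frame−1, Frame−1+round(lifetime/interval))`, with E/S/R phase frame
counts applied sequentially (overshoot from rounding is trimmed from the
tail phases and flagged). The directional parameters of the centroid
subpath — ND, TPL, STA = ND/TPL, PR (mean cosine of turning angles),
ANGVAR (circular variance of turning angles), TI (mean |turning angle|/π),
TP15 … TP85 (fractions of turning angles above 15° … 85° in 10° steps) and
average speed — are *named but not defined* in the source; the definitions
above are the standard motility metrics, implemented in one function so
alternatives can be swapped, and recorded in output metadata. Columns are
z-scored (constant columns dropped with a warning, using a relative spread
guard so numerically-constant columns do not amplify rounding noise into
z), PCA is computed by SVD, and PC1's sign is anchored so it correlates
non-negatively with ND — the most direct proxy of "stronger directional
migration". CDI is the row mean of the z-scores; the median split assigns
ties and exact-median rows to the low state, deterministically. Cell-level
stratification reuses the same machinery on per-cell aggregated parameters.
Transition probabilities P(A→B) and run lengths are first-order summaries
of each cell's onset-ordered state sequence.

## The synthetic generator

The generator exists so every stage above is testable without imaging
data. A cell is a star-convex radial boundary: a base circle of radius
6 µm (resting curvature 0.167 µm⁻¹, safely below the 0.2 µm⁻¹ detector
threshold; a 5 µm cell would rest exactly at threshold) plus raised-cosine
bumps whose amplitudes ramp linearly over the scripted expansion frames,
hold through stabilization, and decay over retraction. Scripted events are
placed at the instantaneous leading edge (heading at birth, with jitter),
as pseudopods are in vivo; combined with slow, persistent default motion in
the scripted-event conditions (0.1 µm/s, persistence 0.95) this makes the
boundary dynamics at the bump dominated by the schedule, so the scripted
E+S duration is the ground truth for the detected lifetime. The centroid
follows a correlated random walk whose turning angles are wrapped-normal
with expected cosine equal to the persistence parameter, so the direction
autocorrelation decays approximately as persistence^Δt. The cortical field
is a uniform interior background plus a rear pool (raised-cosine around the
anti-heading) and a front pool whose level fluctuates as a clipped AR(1)
process. Rendering voxelizes the field (the star-convex inside test is
exact), blurs with a Gaussian point-spread of 0.3 µm, and applies Poisson
and Gaussian noise; single-plane stacks are the default since the analysis
works on max-projections. Everything is bit-reproducible given the seed.

What the generator does *not* emulate: cortex mechanics, membrane-proximal
vs cytoplasmic signal mixing, collagen fibre structure (the optional matrix
channel is a static blurred texture for registration tests), protrusion
branching, and z-dependent optics. Passing tests on these fixtures
therefore demonstrate the correctness of the measurement machinery, not
biological realism of the inputs.

## Numerical choices and problem sizes

Pratt fits solve a 4×4 generalized eigenproblem on mean-centred
coordinates; collinear windows give zero curvature. Registration uses FFT
cross-correlation against the fixed first frame with parabolic subpixel
refinement; reported shifts are content displacements, and applying them
exactly undoes the drift. Frame-to-frame point tracking searches all 100
cyclic shifts exhaustively. Bootstrap CIs can be restricted to the peak
offset (`ci = "peak"`) when only peak validity matters, which keeps
100-replicate null calibrations cheap. The shipped tests and the
acceptance script use desk-scale problem sizes chosen to exercise every
code path with comfortable statistical margins: 8–30-frame movies, 20-cell
protrusion-recovery populations, 50-cell persistence recovery, 200-subpath
directionality populations, 100-replicate bootstrap nulls at B = 1000.

## Known limitations

Cortical quantification is 2D (projected), as in the original workflow;
touching cells are excluded rather than resolved; the E/S/R phase
durations of detected events are estimated from the centre-rate profile
(expansion while the rate exceeds ε·peak, stabilization for the rest of
the lifetime, retraction for the trailing negative-rate frames) — a
surrogate for a phase detector the source does not define; and the
"NMII load" of a window is implemented as the time-integral of the
region's normalized level, labelled as such, since no formula is printed
for it.
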