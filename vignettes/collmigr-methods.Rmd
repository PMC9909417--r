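---
title: "Quantifying collective migration and single-cell dispersion: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying collective migration and single-cell dispersion: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(collmigr)
```

# The measurement problem

In a spheroid outgrowth assay, a multicellular aggregate is plated on a
2D substrate and its cells spread outward over a day of time-lapse
imaging. Three aspects of that motion carry the biology: how fast and
how far cells move, whether their directions are biased by the
substrate (contact guidance on aligned fibers), and whether cells stay
in the collective or disperse as singles. `collmigr` computes all three
from the output of an upstream nucleus tracker — a table of
`(spot_id, track_id, x, y, frame)` rows — and deliberately never
touches pixels: detection and linking are a solved problem upstream
(Laplacian-of-Gaussian spot detection plus linear-assignment-problem
linking in trackers like TrackMate), and consuming their standard
export keeps the package tracker-agnostic.

# Data model and conventions

Positions are stored in microns; frames as integers. Time is always
derived as `frame * frame_interval` rather than stored, so resampled
or gap-closed data cannot drift. The coordinate origin is the
tracker's (image top-left); no re-centering on the spheroid is done,
because every implemented metric is translation-invariant. Whether the
y axis points down (image convention) or up (mathematical convention)
is not knowable from the table itself, so it is explicit configuration:
`calibration(flip_y = )` mirrors y about the data midline on read,
which preserves every distance and flips the sign of every angle.
Angles are degrees in `(-180, 180]`, measured counter-clockwise from
+x; fiber orientation is an axial quantity in `(-90, 90]` (a fiber at
110° *is* the fiber at −70°), with 90° the convention for vertically
aligned mats.

Tracker exports routinely contain spots the linker never assigned to a
track; these are dropped and counted, not treated as errors. Newer
export dialects insert auxiliary unit/label rows directly under the
column header; the reader skips any contiguous block of rows whose
frame field is non-numeric, which tolerates both the classic
single-header and the multi-header dialects without a version switch.

# Migration metrics

"Directionality" means three different things in common usage, so the
package names them apart and computes all three:

- the **step angle** (instantaneous direction of one displacement);
- the **net direction** (angle of last-minus-first position);
- the **directionality ratio** (Euclidean / accumulated distance,
  1 for straight paths).

Mean speed is accumulated distance over total elapsed time rather than
the mean of per-step speeds: the two agree exactly under uniform
sampling, but the former remains meaningful when the linker closed
gaps and steps have unequal durations. The identity "dt-weighted mean
of instantaneous speeds equals mean speed" holds exactly under these
definitions and is asserted in the tests.

Zero-length steps have speed 0 but no direction; they are excluded from
every angular statistic rather than assigned an arbitrary angle. Polar
histograms use equal-width half-open bins `[lo, hi)` over
`(-180, 180]` with the last bin closed at 180, a convention stated so
results are bit-reproducible.

The speed-binned directionality analysis partitions tracks into four
classes at the quartiles of per-track mean speed (explicit edges can be
given instead — quartiles are the default because published speed-bin
edges for such figures are typically not printed) and attaches each
class's pooled step-angle distribution. A substrate with a uniform
contact-guidance response shows concentration about the fiber axis in
*every* class.

Contact guidance is summarized by the nematic alignment order
$S = \langle \cos 2(\theta - \phi) \rangle$ over step angles $\theta$
about the fiber axis $\phi$. The doubled angle makes the statistic
axial (motion along the fibers in either direction counts equally):
$S = 1$ parallel, $0$ isotropic, $-1$ perpendicular. For an axial von
Mises distribution with concentration $\kappa$, the expectation is the
Bessel ratio $I_1(\kappa)/I_0(\kappa)$ — the closed form used as an
independent oracle in the tests.

# Single-cell dispersion

A nucleus is "single" in a frame when its nearest-neighbour distance
(all-pairs Euclidean, computed with `stats::dist`) is *strictly*
greater than the threshold; equality counts as group, so boundary
behaviour is reproducible bit-for-bit. A lone nucleus in a frame is
single. The threshold is intentionally user-set — it encodes cell size,
magnification and morphology, and the established way to choose it is a
sweep (30/50/100 µm) plus visual comparison of the rendered overlay
against phase-contrast video; 40 µm is a sensible default for
MDA-MB-231-sized cells. Raising the threshold can only shrink the
single set, a set-containment invariant the tests enforce on every
frame.

Classification is per-frame and memoryless: a cell may be single at one
time point and group later, because the definition is geometric, not
historical. A per-track majority label is offered purely as a reporting
convenience (`split_metrics_by_class(per_track = TRUE)`). Class-split
statistics assign each step the class of its track at the step's *end*
frame; the per-frame weighted-mean identity
`n_single * mean_single + n_group * mean_group = n_total * mean_all`
then holds exactly and is asserted on random tables.

Overlay rendering is a deterministic manual rasterizer (fixed
world-to-pixel mapping from the global bounding box, grey group discs,
coloured single discs, a 3×5-pixel bitmap font for the frame/threshold
stamp) written to lossless PNG. A graphics device was deliberately
avoided: font rendering varies across platforms, while pure arithmetic
makes repeated runs byte-identical — which the tests verify with file
checksums. The contract is the per-frame raster; an animated container
(GIF/AVI) is out of scope and can be assembled externally from the PNG
sequence.

# The synthetic spheroid generator

`simulate_spheroid()` is a first-class module, not a test fixture: it
generates tracks with exactly the statistical structure the measurement
code assumes, plus ground truth per observation.

Cells start equally spaced on the rim of a disk (the spheroid body
itself is not simulated — the opaque core is not trackable in the real
assay either) heading radially outward, and new cells appear on the rim
at `release_rate` per frame (fractional rates accumulate
deterministically). Each frame, a group cell draws a heading by
combining two circular densities — persistence (von Mises about its
previous heading, concentration `persistence_kappa`) and substrate bias
(axial von Mises toward `fiber_axis_deg`, concentration
`fiber_bias_kappa`) — multiplied and sampled by rejection with the
persistence kernel as proposal. This combination is exact, and reduces
to either kernel when the other's concentration is zero. Group cells
that stray beyond `cohesion_radius` from their nearest group neighbour
are pulled back to that distance along the connecting line.

Per-cell speeds are lognormal (`speed_mean`, `speed_cv`) and fixed per
cell rather than per step, so speed-bin analyses see genuine
between-cell structure. Von Mises draws use the Best–Fisher rejection
algorithm implemented in-package (no circular-statistics dependency);
all candidate draws consume the RNG stream whether accepted or not, so
output is reproducible, and cells are updated in track-id order from
one global stream, so adding a later cell never perturbs an earlier
cell's draws within a frame.

Detachment is decided at the start of a cell's update: with probability
`p_detach` per frame, a group cell permanently becomes single, its
speed is multiplied by `detach_speed_factor`, and its *first* detached
step escapes radially outward; afterwards it follows persistence and
substrate bias with no cohesion. Deciding detachment before the move
(rather than after) keeps the emitted geometry consistent with the
ground-truth label from the first single-labelled frame onward —
otherwise every detachment event would necessarily produce at least one
observation labelled single while still sitting inside the group, and
no classifier could recover the labels. Detachment is absorbing in the
generator even though the classifier is memoryless; that keeps ground
truth unambiguous, and rejoining behaviour remains testable by running
the classifier on tracks the generator steers back.

Finally, Gaussian localization jitter (`position_noise_sd`) is added to
emitted positions only, leaving the dynamics clean.

## Default parameters

The defaults emulate a 24 h, 30-min-cadence assay: 60 initial + 5
cells/frame over 48 frames gives ~300 tracked cells at the end, inside
the 200–800 nuclei/frame range typical of such experiments;
`spheroid_radius = 150` µm matches a ~1000-cell aggregate;
`speed_mean = 0.3` µm/min with `speed_cv = 0.3` is representative of
invasive breast-cancer lines; `persistence_kappa = 2` gives visibly
persistent but noisy paths; `p_detach = 0.01`/frame with
`detach_speed_factor = 2` yields a few-percent single-cell fraction by
the end; `position_noise_sd = 0.5` µm is sub-pixel localization error;
`cohesion_radius = 25` µm keeps group nearest-neighbour distances well
under the 40 µm classification default.

For classifier ground-truth recovery runs (tests and the acceptance
script) the config instead uses `persistence_kappa = 12` and
`detach_speed_factor = 14`: the recovery property presumes detached
cells actually stay separated from all others by more than the
threshold, and at low persistence wandering singles re-approach the
expanding sheet, violating that premise by construction rather than
through any classifier error.

## What the generator does and does not emulate

It reproduces the signatures the pipeline measures: outward radial
spreading, a growing cell census, persistent biased walks whose pooled
alignment matches the Bessel-ratio closed form, heterogeneous per-cell
speeds, and geometrically separated detached singles. It has no
mechanics (forces, adhesion, traction), no proliferation or death, no
3D, and no fiber-mat images. Passing tests therefore demonstrate that
the *measurement* code is correct on data with known structure — not
that real cells behave like the model; on real data, segmentation and
linking errors upstream (merged nuclei, broken tracks) are additional
error sources the simulator intentionally does not model.

# Numerical choices and degenerate inputs

- Undefined quantities are `NA` markers, never sentinel numbers: angle
  of a zero-length step, directionality ratio of a track that never
  moved, SEM from fewer than two cells, nearest-neighbour distance of a
  lone nucleus, mean speed of a single-observation track.
- Quartile speed bins with tied speeds collapse into one occupied bin
  (via `findInterval` with closed right edge); explicit edges must be
  strictly increasing.
- Tables round-trip through CSV at full `as.character` precision (15
  significant digits); `NaN` is serialized literally because R's CSV
  writer would otherwise fold it into `NA`.
- `filter_tracks` defaults (`min_points = 2`, `min_accumulated_um = 0`)
  remove only single-observation tracks — the minimal cleaning that the
  rest of the pipeline requires. Anything stricter (e.g. removing
  immotile debris by a distance floor) is available but off by default,
  since dead-cell removal is usually done upstream by masking before
  tracking.
- The full pipeline asserts a bookkeeping identity on every run: steps
  rows = spot rows − track count. The run manifest contains no
  timestamps, so reruns on identical input are byte-identical.

# Problem sizes

The test suite and acceptance script run at sizes chosen to exercise
the statistics properly while staying desk-scale: 200 random frames of
up to 500 nuclei for the classifier-oracle comparison, 10⁴ draws for
distributional recovery (sampling error ~2/√n ≈ 0.02 on the alignment
order), 48-frame simulations with 80–300 cells for ground-truth
recovery, and ten simulated spheroids for the end-to-end determinism
check.

# Known limitations

- The classifier is strictly nearest-neighbour-distance thresholding —
  no k>1 graphs, DBSCAN-style clustering or sheet segmentation — by
  design, matching the established dispersion measure this package
  implements.
- No automatic threshold selection; the sweep plus overlay inspection
  is the supported workflow.
- No hypothesis testing between conditions: outputs are plain tables so
  any statistics tool can consume them (`aggregate_runs()` prepares the
  per-condition stacking).
- Angular statistics assume 2D motion in the imaging plane.
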