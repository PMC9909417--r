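# collmigr

Quantifying collective cell migration from nuclear tracks.

When a multicellular spheroid is plated on a 2D substrate — glass, or
electrospun fiber mats mimicking the fibrous extracellular matrix — its
cells spread outward while initially retaining cell–cell contacts, and
some break away as single cells. Time-lapse imaging of a nuclear stain,
followed by spot detection and frame-to-frame linking in a tracker such
as TrackMate, yields a table of nucleus positions over time. `collmigr`
takes it from there: it turns per-nucleus tracking tables into the
migration statistics that characterize collective motion, contact
guidance and single-cell dispersal.

The package is aimed at cell-migration labs running spheroid outgrowth
(or scratch/wound-type) assays who want reproducible, scriptable
quantification downstream of their tracker.

## What it computes

For each track with positions $p_0, \dots, p_{n-1}$ at times $t_i$:

- **accumulated distance** $d_{acc} = \sum_i \lVert p_{i+1} - p_i \rVert$
  and **Euclidean distance** $d_{euc} = \lVert p_{n-1} - p_0 \rVert$;
- **mean speed** $d_{acc} / (t_{n-1} - t_0)$ and the median of per-step
  speeds;
- **directionality ratio** $d_{euc} / d_{acc} \in [0, 1]$ (1 = perfectly
  straight), plus per-step direction angles and the net direction;
- per-frame **instantaneous speed** series (mean ± SEM over cells) and
  cell census;
- **polar probability distributions** of motion direction, and the
  four-bin **speed-binned directionality** analysis that checks whether
  fast and slow cells respond differently to a directional cue;
- a nematic **alignment order parameter**
  $S = \langle \cos 2(\theta - \phi) \rangle$ about the fiber axis
  $\phi$ (1 = all motion along the fibers, 0 = isotropic, −1 =
  perpendicular), the scalar summary of contact guidance;
- per-frame **single-cell classification**: a nucleus whose
  nearest-neighbour distance within its frame exceeds a user-set
  threshold (default 40 µm) is "single", otherwise "group"; from this,
  dispersion time series (counts and single/total ratio), threshold
  sweeps, class-split speed/directionality, and grey-vs-colour overlay
  renderings for visual validation of the threshold.

An agent-based simulator (`simulate_spheroid()`) generates synthetic
outgrowth tracks — outward spreading, persistent headings, axial von
Mises contact-guidance bias, lognormal cell speeds, stochastic
detachment — with per-observation ground truth, so every stage of the
pipeline can be validated without microscopy data.

## Worked example

```r
library(collmigr)

# simulate one spheroid on an aligned-fiber substrate (fibers at 90 deg)
sim <- simulate_spheroid(sim_config(n_cells_initial = 60, release_rate = 5,
                                    n_frames = 48, fiber_bias_kappa = 3,
                                    p_detach = 0.01, seed = 7))
tab <- sim$table

m <- track_metrics(tab)
summary(m$mean_speed)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.    NA's 
#>  0.1382  0.2599  0.3138  0.3451  0.4077  0.8868       5 

s <- compute_steps(tab)
alignment_order(s$angle_deg, 90)
#> [1] 0.8086329

d <- dispersion_timeseries(tab, threshold = 40)
tail(d[c("frame", "n_total", "n_single", "ratio")], 3)
#>    frame n_total n_single      ratio
#> 46    45     285       14 0.04912281
#> 47    46     290       12 0.04137931
#> 48    47     295       13 0.04406780
```

Mean speeds of ~0.3 µm/min are typical of invasive breast cancer cells
(the 5 `NA`s are cells released in the final frame, which have no
elapsed time yet); the alignment order of 0.81 reflects the strong
contact-guidance bias (`fiber_bias_kappa = 3`) of this simulated
aligned substrate; by the last frame, 13 of 295 tracked cells (4.4 %)
have detached from the collective at the 40 µm nearest-neighbour
threshold.

With real tracker output instead:

```r
cal <- calibration(pixel_size = 0.65, frame_interval = 30, fiber_axis_deg = 90)
tab <- read_spot_table("spots.csv", cal, unit = "pixel")
tab <- filter_tracks(tab)             # drop single-observation tracks
run_full_analysis("spots.csv", run_config(cal, sweep_thresholds = c(30, 50, 100)),
                  output_dir = "results_spheroid1")
```

which writes every table (steps, per-track metrics, instantaneous
series, polar and speed-binned distributions, dispersion series and
sweep, class-split statistics), the overlay frames, and a JSON manifest
with a config snapshot, input checksum and per-stage row counts.

A shell wrapper with `simulate` / `metrics` / `polar` / `dispersion` /
`analyze` / `aggregate` subcommands is installed at
`system.file("cli", "collmigr.R", package = "collmigr")`.

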