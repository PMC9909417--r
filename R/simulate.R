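#' Configuration for the synthetic spheroid-outgrowth simulator
#'
#' Parameters of an agent-based model of cells migrating outward from a
#' spheroid plated on a 2D substrate. The defaults emulate a typical
#' breast-cancer spheroid assay imaged every 30 minutes for 24 hours:
#' a few hundred trackable cells, speeds of a few tenths of a micron per
#' minute with cell-to-cell heterogeneity, persistent but noisy
#' headings, optional contact-guidance bias toward a fiber axis, and
#' occasional permanent detachment of single cells that then move
#' faster than the collective.
#'
#' @param n_cells_initial Cells seeded on the spheroid rim at frame 0.
#' @param release_rate Cells per frame newly emitted from the rim
#'   (fractional rates accumulate deterministically).
#' @param spheroid_radius Spheroid rim radius, microns.
#' @param n_frames Number of frames (30-min cadence over 24 h gives 48).
#' @param frame_interval Minutes per frame.
#' @param speed_mean,speed_cv Mean and coefficient of variation of the
#'   per-cell lognormal speed distribution (um/min). Speeds are fixed
#'   per cell, giving real between-cell structure for speed-bin
#'   analyses.
#' @param persistence_kappa Von Mises concentration of each step's
#'   heading about the previous heading; 0 is an uncorrelated random
#'   walk.
#' @param fiber_bias_kappa Axial von Mises concentration of headings
#'   toward `fiber_axis_deg`; 0 models an isotropic substrate (glass,
#'   random fibers).
#' @param fiber_axis_deg Fiber axis orientation, degrees.
#' @param p_detach Per-cell per-frame probability that a group cell
#'   permanently detaches.
#' @param detach_speed_factor Speed multiplier applied on detachment.
#' @param cohesion_radius Maximum distance a group cell may stray from
#'   its nearest group neighbour before being pulled back, microns.
#' @param position_noise_sd Gaussian localization jitter added to
#'   emitted positions, microns.
#' @param seed Integer RNG seed; identical config + seed reproduces the
#'   output bit for bit.
#'
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_cells_initial = 60L,
                       release_rate = 5,
                       spheroid_radius = 150,
                       n_frames = 48L,
                       frame_interval = 30,
                       speed_mean = 0.3,
                       speed_cv = 0.3,
                       persistence_kappa = 2,
                       fiber_bias_kappa = 0,
                       fiber_axis_deg = 90,
                       p_detach = 0.01,
                       detach_speed_factor = 2,
                       cohesion_radius = 25,
                       position_noise_sd = 0.5,
                       seed = 1L) {
  cfg <- list(n_cells_initial = as.integer(n_cells_initial),
              release_rate = release_rate,
              spheroid_radius = spheroid_radius,
              n_frames = as.integer(n_frames),
              frame_interval = frame_interval,
              speed_mean = speed_mean, speed_cv = speed_cv,
              persistence_kappa = persistence_kappa,
              fiber_bias_kappa = fiber_bias_kappa,
              fiber_axis_deg = normalize_axis_deg(fiber_axis_deg),
              p_detach = p_detach,
              detach_speed_factor = detach_speed_factor,
              cohesion_radius = cohesion_radius,
              position_noise_sd = position_noise_sd,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_cells_initial >= 1L, release_rate >= 0, spheroid_radius > 0,
              n_frames >= 1L, frame_interval > 0, speed_mean > 0,
              speed_cv >= 0, persistence_kappa >= 0, fiber_bias_kappa >= 0,
              p_detach >= 0, p_detach <= 1, detach_speed_factor > 0,
              cohesion_radius > 0, position_noise_sd >= 0)
  })
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# Draw one heading (radians) combining persistence about `prev` with an
# axial bias toward `axis` (radians): densities multiply; the persistence
# kernel is the rejection proposal, the axial factor the acceptance
# weight (bounded by exp(kappa_b)).
draw_heading <- function(prev, kappa_p, axis, kappa_b) {
  repeat {
    cand <- if (kappa_p < 1e-10) stats::runif(1, -pi, pi) else
      rvonmises(1L, prev, kappa_p)
    if (kappa_b < 1e-10) return(cand)
    if (stats::runif(1) <= exp(kappa_b * (cos(2 * (cand - axis)) - 1))) {
      return(cand)
    }
  }
}

#' Simulate spheroid outgrowth tracks with ground truth
#'
#' Runs the agent-based model described in [sim_config()] and emits a
#' calibrated [track_table()] (what an upstream nucleus tracker would
#' produce) together with the generator's ground truth for every
#' observation, enabling recovery tests of every downstream stage.
#'
#' Model outline, per frame: newly released cells appear on the rim
#' heading radially outward; each group cell draws a heading combining
#' persistence with the substrate's axial bias and steps by its speed;
#' group cells that stray beyond `cohesion_radius` of their nearest
#' group neighbour are pulled back to that distance; each group cell
#' may permanently detach (decided before it moves, the first detached
#' step escaping radially outward at the boosted speed, so the emitted
#' geometry agrees with the ground-truth label from the first single
#' frame onward); finally Gaussian localization noise is added to the
#' emitted positions. Detachment is absorbing — singles never rejoin —
#' which keeps the ground truth unambiguous even though the downstream
#' classifier is memoryless. Cells are updated in track-id order from
#' one global RNG stream, so adding a later cell never perturbs an
#' earlier cell's draws within a frame.
#'
#' @param config A [sim_config()].
#' @param source_label Label stored on the emitted table.
#' @return A list with `table` (a [track_table()]) and `truth`, a list
#'   with `per_observation` (data.frame `track_id`, `frame`, `class`),
#'   `per_track` (data.frame `track_id`, `true_speed`), and the global
#'   `fiber_axis_deg` / `fiber_bias_kappa`.
#' @export
simulate_spheroid <- function(config = sim_config(), source_label = "simulated") {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(cfg$seed)

  axis_rad <- cfg$fiber_axis_deg * pi / 180
  sdlog <- sqrt(log(1 + cfg$speed_cv^2))
  meanlog <- log(cfg$speed_mean) - sdlog^2 / 2
  draw_speed <- function() stats::rlnorm(1, meanlog, sdlog)

  # cell state vectors, indexed by track id
  x <- y <- heading <- speed <- numeric(0)
  cls <- character(0)   # "group" / "single"

  spawn <- function(rim_angle) {
    x <<- c(x, cfg$spheroid_radius * cos(rim_angle))
    y <<- c(y, cfg$spheroid_radius * sin(rim_angle))
    heading <<- c(heading, rim_angle)  # outward
    speed <<- c(speed, draw_speed())
    cls <<- c(cls, "group")
  }
  for (i in seq_len(cfg$n_cells_initial)) {
    spawn(2 * pi * (i - 1) / cfg$n_cells_initial)
  }

  obs <- vector("list", cfg$n_frames)
  truth <- vector("list", cfg$n_frames)
  emit <- function(frame) {
    n <- length(x)
    ex <- x + stats::rnorm(n, 0, cfg$position_noise_sd)
    ey <- y + stats::rnorm(n, 0, cfg$position_noise_sd)
    obs[[frame + 1L]] <<- data.frame(
      spot_id = frame * 100000L + seq_len(n), track_id = seq_len(n),
      x = ex, y = ey, frame = frame)
    truth[[frame + 1L]] <<- data.frame(track_id = seq_len(n), frame = frame,
                                       class = cls)
  }
  emit(0L)

  release_carry <- 0
  step_len <- function(id) speed[id] * cfg$frame_interval
  for (f in seq_len(cfg$n_frames - 1L)) {
    release_carry <- release_carry + cfg$release_rate
    k <- floor(release_carry)
    release_carry <- release_carry - k
    if (k > 0) for (j in seq_len(k)) spawn(stats::runif(1, 0, 2 * pi))

    for (id in seq_along(x)) {
      if (cls[id] == "group" && stats::runif(1) < cfg$p_detach) {
        # detach now: escape radially outward at boosted speed
        cls[id] <- "single"
        speed[id] <- speed[id] * cfg$detach_speed_factor
        heading[id] <- atan2(y[id], x[id])
      } else {
        heading[id] <- draw_heading(heading[id], cfg$persistence_kappa,
                                    axis_rad, cfg$fiber_bias_kappa)
      }
      x[id] <- x[id] + step_len(id) * cos(heading[id])
      y[id] <- y[id] + step_len(id) * sin(heading[id])
    }

    # cohesion: group cells pulled back toward their nearest group
    # neighbour when beyond cohesion_radius (sequential, id order)
    grp <- which(cls == "group")
    if (length(grp) >= 2L) {
      for (id in grp) {
        others <- setdiff(grp, id)
        d2 <- (x[others] - x[id])^2 + (y[others] - y[id])^2
        jmin <- others[which.min(d2)]
        d <- sqrt(min(d2))
        if (d > cfg$cohesion_radius) {
          frac <- (d - cfg$cohesion_radius) / d
          x[id] <- x[id] + frac * (x[jmin] - x[id])
          y[id] <- y[id] + frac * (y[jmin] - y[id])
        }
      }
    }
    emit(f)
  }

  spots <- do.call(rbind, obs)
  cal <- calibration(pixel_size = 1, frame_interval = cfg$frame_interval,
                     fiber_axis_deg = cfg$fiber_axis_deg)
  table <- track_table(spots, calibration = cal, source_label = source_label)
  per_obs <- do.call(rbind, truth)
  per_obs <- per_obs[order(per_obs$track_id, per_obs$frame), , drop = FALSE]
  rownames(per_obs) <- NULL
  list(table = table,
       truth = list(per_observation = per_obs,
                    per_track = data.frame(track_id = seq_along(speed),
                                           true_speed = speed),
                    fiber_axis_deg = cfg$fiber_axis_deg,
                    fiber_bias_kappa = cfg$fiber_bias_kappa))
}

#' Render synthetic nuclei images from a track table
#'
#' Produces, per frame, a grayscale image with a Gaussian intensity blob
#' at each nucleus position plus mild background noise — a synthetic
#' stand-in for a Hoechst nuclear channel, intended for exercising
#' external detection/linking tools. Not used by the internal pipeline.
#'
#' @param table A [track_table()].
#' @param image_size Image side length in pixels (square field).
#' @param psf_sd Gaussian blob scale in microns.
#' @param background_sd Standard deviation of the additive background
#'   noise (image intensity units; drawn from the current RNG stream).
#' @return A numeric array `image_size x image_size x n_frames` with
#'   values clipped to `[0, 1]`. Nuclei outside the field trigger a
#'   warning and are clipped.
#' @export
render_synthetic_nuclei <- function(table, image_size = 256L, psf_sd = 3,
                                    background_sd = 0.01) {
  stopifnot(inherits(table, "track_table"))
  cal <- track_calibration(table)
  frames <- if (nrow(table)) seq(min(table$frame), max(table$frame)) else 0L
  n_f <- length(frames)
  out <- array(0, dim = c(image_size, image_size, n_f))
  px_sd <- psf_sd / cal$pixel_size
  half <- ceiling(4 * px_sd)
  n_clipped <- 0L
  for (i in seq_len(n_f)) {
    img <- matrix(0, image_size, image_size)
    sub <- table[table$frame == frames[i], , drop = FALSE]
    for (j in seq_len(nrow(sub))) {
      cx <- sub$x[j] / cal$pixel_size + 1
      cy <- sub$y[j] / cal$pixel_size + 1
      if (cx < 1 || cx > image_size || cy < 1 || cy > image_size) {
        n_clipped <- n_clipped + 1L
      }
      xs <- max(1L, floor(cx - half)):min(image_size, ceiling(cx + half))
      ys <- max(1L, floor(cy - half)):min(image_size, ceiling(cy + half))
      if (length(xs) == 0L || length(ys) == 0L) next
      gx <- exp(-(xs - cx)^2 / (2 * px_sd^2))
      gy <- exp(-(ys - cy)^2 / (2 * px_sd^2))
      img[ys, xs] <- img[ys, xs] + outer(gy, gx)
    }
    img <- img + matrix(abs(stats::rnorm(image_size^2, 0, background_sd)),
                        image_size, image_size)
    out[, , i] <- pmin(img, 1)
  }
  if (n_clipped > 0L) {
    warning(sprintf("%d nuclei outside the %dx%d px field were clipped",
                    n_clipped, image_size, image_size))
  }
  out
}
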