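#' Decompose tracks into displacement steps
#'
#' One step per consecutive pair of observations within a track. Steps
#' are gap-aware: when the upstream linker closed a gap, `dt` spans the
#' actual frame difference, so speeds stay in microns per minute
#' regardless of missing frames. Tracks with a single observation
#' produce no steps. Zero-length steps have speed 0 and an undefined
#' direction (`angle_deg = NA`): a stationary nucleus has no direction,
#' and inventing one would contaminate every angular statistic.
#'
#' @param table A [track_table()].
#' @return A data.frame of class `"step_table"` with columns `track_id`,
#'   `frame_from`, `frame_to`, `dt` (min), `dx`, `dy`, `step_length`
#'   (um), `speed` (um/min) and `angle_deg` in `(-180, 180]` measured
#'   counter-clockwise from +x.
#' @export
compute_steps <- function(table) {
  stopifnot(inherits(table, "track_table"))
  cal <- track_calibration(table)
  if (nrow(table) == 0L) {
    out <- data.frame(track_id = integer(), frame_from = integer(),
                      frame_to = integer(), dt = numeric(), dx = numeric(),
                      dy = numeric(), step_length = numeric(),
                      speed = numeric(), angle_deg = numeric())
    return(structure(out, calibration = cal,
                     class = c("step_table", "data.frame")))
  }
  # table is canonically sorted by (track_id, frame); consecutive rows of
  # the same track are consecutive observations.
  same <- c(FALSE, table$track_id[-1L] == table$track_id[-nrow(table)])
  to <- which(same)
  from <- to - 1L
  dframes <- table$frame[to] - table$frame[from]
  dt <- dframes * cal$frame_interval
  dx <- table$x[to] - table$x[from]
  dy <- table$y[to] - table$y[from]
  len <- sqrt(dx^2 + dy^2)
  ang <- normalize_angle_deg(atan2(dy, dx) * 180 / pi)
  ang[len == 0] <- NA_real_
  out <- data.frame(
    track_id = table$track_id[to],
    frame_from = table$frame[from],
    frame_to = table$frame[to],
    dt = dt, dx = dx, dy = dy,
    step_length = len,
    speed = len / dt,
    angle_deg = ang
  )
  rownames(out) <- NULL
  structure(out, calibration = cal, class = c("step_table", "data.frame"))
}

#' Per-track migration summaries
#'
#' Computes the classic per-cell migration metrics. Mean speed is
#' accumulated distance over total elapsed time (not the mean of
#' per-step speeds), which is robust to gap-closed tracks with unequal
#' step durations and identical to the per-step mean under uniform
#' sampling. The directionality ratio (Euclidean over accumulated
#' distance) is 1 for perfectly straight motion; it is undefined (`NA`)
#' for a track that never moved, as is the net direction.
#'
#' @param table A [track_table()].
#' @return A data.frame with one row per track: `track_id`, `n_points`,
#'   `total_time` (min), `accumulated_distance` (um),
#'   `euclidean_distance` (um), `mean_speed`, `median_speed` (um/min),
#'   `directionality_ratio` in `[0, 1]`, and `net_direction_deg`.
#' @export
track_metrics <- function(table) {
  stopifnot(inherits(table, "track_table"))
  cal <- track_calibration(table)
  empty <- data.frame(track_id = integer(), n_points = integer(),
                      total_time = numeric(), accumulated_distance = numeric(),
                      euclidean_distance = numeric(), mean_speed = numeric(),
                      median_speed = numeric(), directionality_ratio = numeric(),
                      net_direction_deg = numeric())
  if (nrow(table) == 0L) return(empty)
  rows <- lapply(split(table[c("x", "y", "frame")], table$track_id), function(d) {
    n <- nrow(d)
    total_time <- (d$frame[n] - d$frame[1L]) * cal$frame_interval
    if (n >= 2L) {
      step_len <- sqrt(diff(d$x)^2 + diff(d$y)^2)
      step_dt <- diff(d$frame) * cal$frame_interval
      accum <- sum(step_len)
      med <- stats::median(step_len / step_dt)
    } else {
      accum <- 0
      med <- NA_real_
    }
    ex <- d$x[n] - d$x[1L]
    ey <- d$y[n] - d$y[1L]
    euclid <- sqrt(ex^2 + ey^2)
    data.frame(
      n_points = n,
      total_time = total_time,
      accumulated_distance = accum,
      euclidean_distance = euclid,
      mean_speed = if (total_time > 0) accum / total_time else NA_real_,
      median_speed = med,
      directionality_ratio = if (accum > 0) euclid / accum else NA_real_,
      net_direction_deg = if (euclid > 0)
        normalize_angle_deg(atan2(ey, ex) * 180 / pi) else NA_real_
    )
  })
  out <- do.call(rbind, rows)
  out <- cbind(track_id = as.integer(names(rows)), out)
  rownames(out) <- NULL
  out
}

#' Instantaneous population time series
#'
#' For each frame after the first, aggregates every step that ends at
#' that frame: the number of tracks contributing, the mean and standard
#' error of their instantaneous speeds, and the nematic alignment of
#' their step directions with the calibrated fiber axis (see
#' [alignment_order()]). Frames where no step ends are omitted. The SEM
#' uses the n-1 variance and is `NA` when fewer than two cells
#' contribute.
#'
#' @param table A [track_table()].
#' @return A data.frame with columns `frame`, `n_cells`, `mean_speed`,
#'   `sem_speed` (um/min) and `mean_alignment`.
#' @export
instantaneous_series <- function(table) {
  stopifnot(inherits(table, "track_table"))
  cal <- track_calibration(table)
  steps <- compute_steps(table)
  empty <- data.frame(frame = integer(), n_cells = integer(),
                      mean_speed = numeric(), sem_speed = numeric(),
                      mean_alignment = numeric())
  if (nrow(steps) == 0L) return(empty)
  rows <- lapply(split(steps, steps$frame_to), function(s) {
    n <- nrow(s)
    ang <- s$angle_deg[!is.na(s$angle_deg)]
    data.frame(
      n_cells = n,
      mean_speed = mean(s$speed),
      sem_speed = if (n >= 2L) stats::sd(s$speed) / sqrt(n) else NA_real_,
      mean_alignment = if (length(ang))
        alignment_order(ang, cal$fiber_axis_deg) else NA_real_
    )
  })
  out <- do.call(rbind, rows)
  out <- cbind(frame = as.integer(names(rows)), out)
  out <- out[order(out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}
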