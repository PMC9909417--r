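# Shared fixtures: all built in code at test time.

# Minimal calibrated table from a spots data.frame.
tt <- function(spots, frame_interval = 30, fiber_axis = 90, ...) {
  track_table(spots, calibration(frame_interval = frame_interval,
                                 fiber_axis_deg = fiber_axis, ...))
}

# The 3-4-5 reference track: (0,0) -> (3,4) -> (9,12) at frames 0, 1, 3.
track_345 <- function(frame_interval = 30) {
  tt(data.frame(spot_id = 1:3, track_id = 0L,
                x = c(0, 3, 9), y = c(0, 4, 12), frame = c(0L, 1L, 3L)),
     frame_interval = frame_interval)
}

# Straight-line track with a prescribed constant speed (um/min).
straight_track <- function(track_id, speed, n_frames, frame_interval = 30,
                           angle_deg = 0, x0 = 0, y0 = 0) {
  step <- speed * frame_interval
  f <- 0:(n_frames - 1)
  data.frame(spot_id = track_id * 10000L + f, track_id = track_id,
             x = x0 + f * step * cos(angle_deg * pi / 180),
             y = y0 + f * step * sin(angle_deg * pi / 180),
             frame = f)
}

# Random-walk table with staggered track entry.
random_track_table <- function(n_tracks = 10, n_frames = 10, seed = 1,
                               field = 200, step_sd = 8, frame_interval = 30,
                               stagger = TRUE) {
  set.seed(seed)
  rows <- lapply(seq_len(n_tracks), function(id) {
    f0 <- if (stagger) sample(0:(n_frames - 1L), 1L) else 0L
    frames <- f0:(n_frames - 1L)
    n <- length(frames)
    data.frame(spot_id = id * 100000L + frames, track_id = id,
               x = stats::runif(1, 0, field) + cumsum(c(0, stats::rnorm(n - 1, 0, step_sd))),
               y = stats::runif(1, 0, field) + cumsum(c(0, stats::rnorm(n - 1, 0, step_sd))),
               frame = frames)
  })
  tt(do.call(rbind, rows), frame_interval = frame_interval)
}

# Independent brute-force nearest-neighbour oracle: per-point minimum
# over explicit pairwise distances, no dist() call.
brute_classify <- function(x, y, threshold) {
  n <- length(x)
  if (n == 0L) return(data.frame(nn = numeric(), label = character()))
  if (n == 1L) return(data.frame(nn = NA_real_, label = "single"))
  nn <- numeric(n)
  for (i in seq_len(n)) {
    nn[i] <- min(sqrt((x[-i] - x[i])^2 + (y[-i] - y[i])^2))
  }
  data.frame(nn = nn, label = ifelse(nn > threshold, "single", "group"))
}

# Write a TrackMate-style spot-statistics file.
write_spot_csv <- function(path, df, sep = ",", extra_header_rows = NULL,
                           col_names = c("ID", "TRACK_ID", "POSITION_X",
                                         "POSITION_Y", "FRAME")) {
  lines <- paste(col_names, collapse = sep)
  if (!is.null(extra_header_rows)) {
    lines <- c(lines, vapply(extra_header_rows,
                             function(r) paste(r, collapse = sep), character(1)))
  }
  body <- apply(df, 1L, function(r) paste(r, collapse = sep))
  writeLines(c(lines, body), path)
  path
}
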