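#' Classify the nuclei of one frame as single or group cells
#'
#' Computes, for every nucleus, the Euclidean distance to its nearest
#' other nucleus in the same frame (all-pairs definition) and labels the
#' nucleus `"single"` when that distance is strictly greater than
#' `threshold`; a nucleus exactly at the threshold is `"group"`, so
#' results are reproducible bit-for-bit. A lone nucleus in a frame has
#' no neighbour and is `"single"` (its `nn_distance` is `NA`).
#'
#' The threshold is deliberately user-set: it encodes how far apart
#' nuclei of touching cells can be for a given cell line and
#' magnification (40 um is a sensible default for MDA-MB-231-sized
#' cells).
#'
#' @param points A data.frame with columns `x`, `y` (microns) and
#'   optionally `spot_id` (defaults to row order).
#' @param threshold Nearest-neighbour distance threshold in microns;
#'   positive.
#' @return A data.frame of class `"frame_classification"` with columns
#'   `spot_id`, `nn_distance` and `label` (`"single"` / `"group"`);
#'   attribute `threshold`.
#' @examples
#' classify_frame(data.frame(x = c(0, 10, 100), y = 0), threshold = 40)
#' @export
classify_frame <- function(points, threshold = 40) {
  if (!is.numeric(threshold) || length(threshold) != 1L || !is.finite(threshold) ||
      threshold <= 0) {
    stop("`threshold` must be a single positive number (microns)", call. = FALSE)
  }
  points <- as.data.frame(points)
  if (!all(c("x", "y") %in% names(points))) {
    stop("`points` must have columns x and y", call. = FALSE)
  }
  n <- nrow(points)
  spot_id <- if ("spot_id" %in% names(points)) points$spot_id else seq_len(n)
  if (n == 0L) {
    out <- data.frame(spot_id = integer(), nn_distance = numeric(),
                      label = character())
  } else if (n == 1L) {
    out <- data.frame(spot_id = spot_id, nn_distance = NA_real_,
                      label = "single")
  } else {
    d <- as.matrix(stats::dist(cbind(points$x, points$y)))
    diag(d) <- Inf
    nn <- apply(d, 1L, min)
    out <- data.frame(spot_id = spot_id, nn_distance = nn,
                      label = ifelse(nn > threshold, "single", "group"))
  }
  rownames(out) <- NULL
  structure(out, threshold = threshold,
            class = c("frame_classification", "data.frame"))
}

#' Classify every frame of a track table
#'
#' Applies [classify_frame()] to each frame present in the table, in
#' frame order, and returns one long table of per-nucleus labels.
#'
#' @param table A [track_table()].
#' @param threshold Nearest-neighbour distance threshold in microns.
#' @return A data.frame with columns `frame`, `spot_id`, `track_id`,
#'   `nn_distance` and `label`; attribute `threshold`.
#' @export
classify_table <- function(table, threshold = 40) {
  stopifnot(inherits(table, "track_table"))
  frames <- sort(unique(table$frame))
  rows <- lapply(frames, function(f) {
    sub <- table[table$frame == f, , drop = FALSE]
    cls <- classify_frame(sub[c("spot_id", "x", "y")], threshold = threshold)
    data.frame(frame = f, spot_id = cls$spot_id,
               track_id = sub$track_id[match(cls$spot_id, sub$spot_id)],
               nn_distance = cls$nn_distance, label = cls$label)
  })
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(frame = integer(), spot_id = integer(), track_id = integer(),
               nn_distance = numeric(), label = character())
  }
  rownames(out) <- NULL
  structure(out, threshold = threshold, class = c("data.frame"))
}

#' Single-cell dispersion time series
#'
#' Per-frame census of detached cells: total nuclei, nuclei labelled
#' single, their ratio, and the single spot IDs. Classification is
#' per-frame and memoryless — a cell that rejoins the group stops being
#' counted as single.
#'
#' @param table A [track_table()].
#' @param threshold Nearest-neighbour distance threshold in microns.
#' @param classified Optional precomputed result of [classify_table()]
#'   (saves recomputation); must match `threshold`.
#' @return A data.frame with columns `frame`, `n_total`, `n_single`,
#'   `ratio` (`NA` when a frame is empty) and list column `single_ids`;
#'   attribute `threshold`.
#' @export
dispersion_timeseries <- function(table, threshold = 40, classified = NULL) {
  stopifnot(inherits(table, "track_table"))
  if (is.null(classified)) classified <- classify_table(table, threshold)
  rows <- lapply(split(classified, classified$frame), function(cf) {
    single <- cf$spot_id[cf$label == "single"]
    n_total <- nrow(cf)
    data.frame(n_total = n_total, n_single = length(single),
               ratio = if (n_total > 0) length(single) / n_total else NA_real_)
  })
  if (length(rows) == 0L) {
    out <- data.frame(frame = integer(), n_total = integer(),
                      n_single = integer(), ratio = numeric())
    out$single_ids <- list()
    return(structure(out, threshold = threshold))
  }
  out <- do.call(rbind, rows)
  out <- cbind(frame = as.integer(names(rows)), out)
  out$single_ids <- lapply(split(classified, classified$frame),
                           function(cf) cf$spot_id[cf$label == "single"])
  out <- out[order(out$frame), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, threshold = threshold)
}

#' Dispersion time series across several thresholds
#'
#' Runs [dispersion_timeseries()] once per threshold and stacks the
#' results, keyed by `(threshold, frame)`. Because the single-cell set
#' can only shrink as the threshold grows, `n_single` is non-increasing
#' in the threshold at every frame — sweeping (e.g. 30, 50, 100 um) is
#' the standard way to pick a threshold for a new cell line.
#'
#' @param table A [track_table()].
#' @param thresholds Numeric vector of positive thresholds in microns.
#' @return A data.frame with columns `threshold`, `frame`, `n_total`,
#'   `n_single`, `ratio` and list column `single_ids`.
#' @export
threshold_sweep <- function(table, thresholds = c(30, 50, 100)) {
  stopifnot(inherits(table, "track_table"))
  if (length(thresholds) == 0L || any(!is.finite(thresholds)) ||
      any(thresholds <= 0)) {
    stop("`thresholds` must be a non-empty vector of positive numbers",
         call. = FALSE)
  }
  rows <- lapply(thresholds, function(th) {
    d <- dispersion_timeseries(table, threshold = th)
    if (nrow(d)) cbind(threshold = th, d) else
      cbind(threshold = numeric(0), d)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Split step statistics by single/group class
#'
#' Assigns every step the class of its track's nucleus at the step's
#' end frame and aggregates, per class and frame, the mean and SEM of
#' instantaneous speed, plus the pooled step angles per class (the
#' per-dot structure behind single-cell directionality plots, ready for
#' [polar_distribution()] or [alignment_order()]).
#'
#' @param table A [track_table()].
#' @param classified Result of [classify_table()] covering every frame
#'   of `table`.
#' @param per_track If `TRUE`, a track's majority label replaces the
#'   per-frame label (reporting convenience; per-frame is the primary
#'   definition).
#' @return A list with `series` (data.frame: `frame`, `label`, `n`,
#'   `mean_speed`, `sem_speed`) and `angles` (data.frame: `frame`,
#'   `track_id`, `label`, `angle_deg`, defined angles only).
#' @export
split_metrics_by_class <- function(table, classified, per_track = FALSE) {
  stopifnot(inherits(table, "track_table"))
  steps <- compute_steps(table)
  if (nrow(steps) == 0L) {
    return(list(
      series = data.frame(frame = integer(), label = character(),
                          n = integer(), mean_speed = numeric(),
                          sem_speed = numeric()),
      angles = data.frame(frame = integer(), track_id = integer(),
                          label = character(), angle_deg = numeric())
    ))
  }
  key_steps <- paste(steps$track_id, steps$frame_to)
  key_cls <- paste(classified$track_id, classified$frame)
  pos <- match(key_steps, key_cls)
  if (anyNA(pos)) {
    bad <- which(is.na(pos))[1L]
    stop(sprintf(
      "integrity error: no classification for track %d at frame %d",
      steps$track_id[bad], steps$frame_to[bad]), call. = FALSE)
  }
  label <- classified$label[pos]
  if (isTRUE(per_track)) {
    maj <- tapply(classified$label == "single", classified$track_id, mean)
    label <- ifelse(maj[as.character(steps$track_id)] > 0.5, "single", "group")
  }
  steps$label <- label

  series <- do.call(rbind, lapply(
    split(steps, list(steps$frame_to, steps$label), drop = TRUE),
    function(s) {
      data.frame(frame = s$frame_to[1L], label = s$label[1L], n = nrow(s),
                 mean_speed = mean(s$speed),
                 sem_speed = if (nrow(s) >= 2L)
                   stats::sd(s$speed) / sqrt(nrow(s)) else NA_real_)
    }))
  series <- series[order(series$frame, series$label), , drop = FALSE]
  rownames(series) <- NULL

  ang <- steps[!is.na(steps$angle_deg),
               c("frame_to", "track_id", "label", "angle_deg")]
  names(ang)[1L] <- "frame"
  ang <- ang[order(ang$frame, ang$track_id), , drop = FALSE]
  rownames(ang) <- NULL

  list(series = series, angles = ang)
}
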