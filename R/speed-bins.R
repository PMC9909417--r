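#' Speed-binned directionality
#'
#' Partitions tracks into speed classes by their per-track mean speed
#' and attaches, to each class, the polar distribution of all step
#' angles of its member tracks. This is the standard check for a
#' speed-directionality correlation: on an aligned substrate a uniform
#' contact-guidance response shows up as every speed class concentrating
#' about the fiber axis.
#'
#' By default the class edges are the quartiles of the per-track mean
#' speeds (`n_bins = 4`); explicit edges can be supplied instead (length
#' `n_bins + 1`, strictly increasing). Tracks with identical speeds at a
#' shared edge all land in the same class.
#'
#' @param table A [track_table()].
#' @param n_bins Number of speed classes (default 4).
#' @param edges Optional explicit speed edges in um/min, length
#'   `n_bins + 1`, strictly increasing.
#' @param polar_bins Number of angular bins for each class's polar
#'   distribution.
#' @return An object of class `"speed_binned_directionality"`: a list
#'   with `bin_edges_speed` and `bins`, where each bin is a list of
#'   `track_ids`, `n_tracks`, and `histogram` (a
#'   [polar_distribution()] over the member tracks' step angles).
#' @export
bin_by_speed <- function(table, n_bins = 4L, edges = NULL, polar_bins = 24L) {
  stopifnot(inherits(table, "track_table"))
  metrics <- track_metrics(table)
  metrics <- metrics[!is.na(metrics$mean_speed), , drop = FALSE]
  if (nrow(metrics) == 0L) {
    stop("no track has a defined mean speed", call. = FALSE)
  }
  ms <- metrics$mean_speed
  if (is.null(edges)) {
    n_bins <- as.integer(n_bins)
    if (n_bins < 1L) stop("`n_bins` must be >= 1", call. = FALSE)
    edges <- unname(stats::quantile(ms, probs = seq(0, 1, length.out = n_bins + 1L)))
  } else {
    if (any(diff(edges) <= 0)) {
      stop("explicit `edges` must be strictly increasing", call. = FALSE)
    }
    n_bins <- length(edges) - 1L
  }
  idx <- findInterval(ms, edges, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), n_bins)

  steps <- compute_steps(table)
  bins <- lapply(seq_len(n_bins), function(b) {
    ids <- metrics$track_id[idx == b]
    ang <- steps$angle_deg[steps$track_id %in% ids]
    ang <- ang[!is.na(ang)]
    list(track_ids = ids,
         n_tracks = length(ids),
         histogram = polar_distribution(ang, n_bins = polar_bins))
  })
  structure(list(bin_edges_speed = edges, bins = bins),
            class = "speed_binned_directionality")
}

#' @export
print.speed_binned_directionality <- function(x, ...) {
  cat(sprintf("<speed_binned_directionality> %d speed classes\n",
              length(x$bins)))
  for (b in seq_along(x$bins)) {
    cat(sprintf("  [%g, %g%s: %d tracks, %d angles\n",
                x$bin_edges_speed[b], x$bin_edges_speed[b + 1L],
                if (b == length(x$bins)) "]" else ")",
                x$bins[[b]]$n_tracks, x$bins[[b]]$histogram$n_angles))
  }
  invisible(x)
}

#' Flatten a speed-binned directionality result to a table
#'
#' One row per speed class per angular bin, suitable for
#' [write_table()].
#'
#' @param x A `"speed_binned_directionality"` object.
#' @return A data.frame with columns `speed_bin`, `speed_lo`, `speed_hi`,
#'   `n_tracks`, `angle_lo`, `angle_hi`, `probability`.
#' @export
speed_bins_as_table <- function(x) {
  stopifnot(inherits(x, "speed_binned_directionality"))
  rows <- lapply(seq_along(x$bins), function(b) {
    h <- x$bins[[b]]$histogram
    k <- length(h$probabilities)
    data.frame(
      speed_bin = b,
      speed_lo = x$bin_edges_speed[b],
      speed_hi = x$bin_edges_speed[b + 1L],
      n_tracks = x$bins[[b]]$n_tracks,
      angle_lo = h$bin_edges_deg[seq_len(k)],
      angle_hi = h$bin_edges_deg[seq_len(k) + 1L],
      probability = h$probabilities
    )
  })
  do.call(rbind, rows)
}
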