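#' Assemble a full-analysis run configuration
#'
#' Defaults are valid without any config file; every field can be
#' overridden from a YAML config (see [read_run_config()]) or, in the
#' command-line wrapper, by a flag (flags win over the file).
#'
#' @param calibration A [calibration()] object.
#' @param min_points,min_accumulated_um Track filtering thresholds, see
#'   [filter_tracks()].
#' @param dispersion_threshold Nearest-neighbour threshold in microns
#'   (default 40).
#' @param sweep_thresholds Optional numeric vector of thresholds for a
#'   sweep (e.g. `c(30, 50, 100)`); `NULL` disables the sweep.
#' @param polar_bins Angular bins for polar distributions.
#' @param speed_bins Number of speed classes for the speed-binned
#'   directionality.
#' @param overlay If `TRUE`, render the per-frame overlay images.
#' @param overlay_width Overlay image width in pixels.
#' @param log_level `"info"` (stage messages with timings to stderr) or
#'   `"quiet"`.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(calibration = collmigr::calibration(),
                       min_points = 2L, min_accumulated_um = 0,
                       dispersion_threshold = 40,
                       sweep_thresholds = NULL,
                       polar_bins = 24L, speed_bins = 4L,
                       overlay = TRUE, overlay_width = 512L,
                       log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  stopifnot(inherits(calibration, "calibration"),
            dispersion_threshold > 0, polar_bins >= 2L, speed_bins >= 1L)
  structure(list(calibration = calibration, min_points = as.integer(min_points),
                 min_accumulated_um = min_accumulated_um,
                 dispersion_threshold = dispersion_threshold,
                 sweep_thresholds = sweep_thresholds,
                 polar_bins = as.integer(polar_bins),
                 speed_bins = as.integer(speed_bins),
                 overlay = isTRUE(overlay),
                 overlay_width = as.integer(overlay_width),
                 log_level = log_level),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Recognized sections: `calibration` (`pixel_size`, `frame_interval`,
#' `flip_y`, `fiber_axis_deg`), `filtering` (`min_points`,
#' `min_accumulated_um`), and top-level `dispersion_threshold`,
#' `sweep_thresholds`, `polar_bins`, `speed_bins`, `overlay`.
#' Unspecified fields keep the [run_config()] defaults.
#'
#' @param path Path to a YAML file.
#' @return A `"run_config"`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  cal_args <- raw$calibration
  cal <- do.call(calibration, if (is.null(cal_args)) list() else cal_args)
  args <- list(calibration = cal)
  filt <- raw$filtering
  if (!is.null(filt$min_points)) args$min_points <- filt$min_points
  if (!is.null(filt$min_accumulated_um))
    args$min_accumulated_um <- filt$min_accumulated_um
  for (nm in c("dispersion_threshold", "sweep_thresholds", "polar_bins",
               "speed_bins", "overlay", "overlay_width", "log_level")) {
    if (!is.null(raw[[nm]])) args[[nm]] <- raw[[nm]]
  }
  do.call(run_config, args)
}

log_stage <- function(config, fmt, ...) {
  if (identical(config$log_level, "info")) {
    message(sprintf("[collmigr %s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...)))
  }
}

#' Run the full migration-analysis workflow
#'
#' Executes the complete pipeline on one tracking table: read, filter,
#' step decomposition, per-track metrics, instantaneous series, polar
#' and speed-binned directionality, single-cell dispersion (plus an
#' optional threshold sweep), class-split statistics, overlay frames,
#' and a JSON run manifest recording the configuration, package
#' version, input checksum and per-stage row counts. All numeric
#' outputs are deterministic: re-running on identical input reproduces
#' identical tables.
#'
#' @param tracks_path Path to a spot-statistics file (see
#'   [read_spot_table()]), or an existing [track_table()].
#' @param config A [run_config()].
#' @param output_dir Directory for the result bundle (created if
#'   needed).
#' @param unit Position unit in the input file, `"um"` or `"pixel"`.
#' @return Invisibly, a list with the in-memory results (`table`,
#'   `steps`, `metrics`, `series`, `polar`, `speed_bins`, `dispersion`,
#'   `sweep`, `split`, `manifest`).
#' @export
run_full_analysis <- function(tracks_path, config = run_config(),
                              output_dir, unit = "um") {
  stopifnot(inherits(config, "run_config"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "read"
  res <- tryCatch({
    if (inherits(tracks_path, "track_table")) {
      table_raw <- tracks_path
      input_md5 <- NA_character_
      input_name <- "<in-memory track_table>"
    } else {
      table_raw <- read_spot_table(tracks_path, config$calibration, unit = unit)
      input_md5 <- unname(tools::md5sum(tracks_path))
      input_name <- tracks_path
    }
    log_stage(config, "read: %d spots, %d tracks", nrow(table_raw),
              length(unique(table_raw$track_id)))

    stage <- "filter"
    table <- filter_tracks(table_raw, config$min_points,
                           config$min_accumulated_um)
    removed <- attr(table, "removal_report")
    log_stage(config, "filter: removed %d tracks", nrow(removed))
    if (nrow(table) == 0L) {
      warning("no tracks remain after filtering; outputs will be empty")
    }

    stage <- "steps"
    steps <- compute_steps(table)
    stage <- "track_metrics"
    metrics <- track_metrics(table)
    # bookkeeping identity: every track contributes one fewer step than
    # observations
    stopifnot(nrow(steps) == nrow(table) - nrow(metrics))
    stage <- "instantaneous_series"
    series <- instantaneous_series(table)

    stage <- "polar"
    ang <- steps$angle_deg[!is.na(steps$angle_deg)]
    polar <- polar_distribution(ang, n_bins = config$polar_bins)
    polar_df <- data.frame(
      angle_lo = polar$bin_edges_deg[-length(polar$bin_edges_deg)],
      angle_hi = polar$bin_edges_deg[-1L],
      probability = polar$probabilities)

    stage <- "speed_bins"
    sbins <- if (nrow(metrics) && any(!is.na(metrics$mean_speed))) {
      bin_by_speed(table, n_bins = config$speed_bins,
                   polar_bins = config$polar_bins)
    } else NULL

    stage <- "dispersion"
    classified <- classify_table(table, config$dispersion_threshold)
    dispersion <- dispersion_timeseries(table, config$dispersion_threshold,
                                        classified = classified)
    sweep <- if (!is.null(config$sweep_thresholds)) {
      threshold_sweep(table, config$sweep_thresholds)
    } else NULL

    stage <- "split_metrics"
    split <- if (nrow(steps)) split_metrics_by_class(table, classified) else NULL

    stage <- "write"
    art <- character(0)
    wt <- function(df, name) {
      write_table(df, file.path(output_dir, name))
      art <<- c(art, name)
    }
    wt(as.data.frame(table), "spots_filtered.csv")
    wt(steps, "steps.csv")
    wt(metrics, "track_metrics.csv")
    wt(series, "instantaneous_series.csv")
    wt(polar_df, "polar_distribution.csv")
    if (!is.null(sbins)) wt(speed_bins_as_table(sbins), "speed_binned_polar.csv")
    wt(dispersion, "dispersion.csv")
    if (!is.null(sweep)) wt(sweep, "dispersion_sweep.csv")
    if (!is.null(split)) {
      wt(split$series, "class_split_series.csv")
      wt(split$angles, "single_group_angles.csv")
    }

    stage <- "overlay"
    if (config$overlay && nrow(table)) {
      paths <- render_overlay(table, classified,
                              file.path(output_dir, "overlay"),
                              width = config$overlay_width)
      log_stage(config, "overlay: %d frames", length(paths))
      art <- c(art, "overlay/")
    }

    stage <- "manifest"
    manifest <- list(
      package = "collmigr",
      version = as.character(utils::packageVersion("collmigr")),
      input = input_name,
      input_md5 = input_md5,
      unit = unit,
      config = list(
        pixel_size = config$calibration$pixel_size,
        frame_interval = config$calibration$frame_interval,
        flip_y = config$calibration$flip_y,
        fiber_axis_deg = config$calibration$fiber_axis_deg,
        min_points = config$min_points,
        min_accumulated_um = config$min_accumulated_um,
        dispersion_threshold = config$dispersion_threshold,
        sweep_thresholds = config$sweep_thresholds,
        polar_bins = config$polar_bins,
        speed_bins = config$speed_bins),
      row_counts = list(
        spots_raw = nrow(table_raw),
        tracks_removed = nrow(removed),
        spots = nrow(table),
        tracks = nrow(metrics),
        steps = nrow(steps),
        series_frames = nrow(series),
        dispersion_frames = nrow(dispersion)),
      artifacts = art)
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
    list(table = table, steps = steps, metrics = metrics, series = series,
         polar = polar, speed_bins = sbins, dispersion = dispersion,
         sweep = sweep, split = split, manifest = manifest)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  log_stage(config, "done: %d artifacts in %s",
            length(res$manifest$artifacts), output_dir)
  invisible(res)
}

#' Aggregate per-track metrics across runs
#'
#' Concatenates the `track_metrics.csv` tables of several completed
#' analysis runs (one spheroid each), adding a `condition` column, so
#' downstream statistics can compare conditions across replicate
#' spheroids.
#'
#' @param run_dirs Character vector of [run_full_analysis()] output
#'   directories.
#' @param conditions Condition label per directory (recycled if length
#'   1).
#' @return A data.frame of stacked per-track metrics with `condition`
#'   and `run` columns.
#' @export
aggregate_runs <- function(run_dirs, conditions) {
  stopifnot(length(run_dirs) >= 1L)
  conditions <- rep_len(conditions, length(run_dirs))
  rows <- lapply(seq_along(run_dirs), function(i) {
    p <- file.path(run_dirs[i], "track_metrics.csv")
    m <- read_result_table(p)
    if (nrow(m)) cbind(condition = conditions[i], run = run_dirs[i], m)
    else cbind(condition = character(0), run = character(0), m)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
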