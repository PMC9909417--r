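#' Construct a calibrated track table
#'
#' A track table is the central currency of the pipeline: one row per
#' observation of one nucleus in one frame, positions in microns, plus a
#' [calibration()] carried as an attribute. Rows are kept canonically
#' sorted by `(track_id, frame)`.
#'
#' @param spots A data.frame with columns `spot_id`, `track_id`, `x`, `y`
#'   (microns) and `frame` (non-negative integer).
#' @param calibration A [calibration()] object.
#' @param source_label Free-text label for the source (e.g. a condition
#'   name such as `"glass"`, `"random"`, `"aligned"`).
#'
#' @return A data.frame of class `"track_table"` with attributes
#'   `calibration` and `source_label`.
#' @export
track_table <- function(spots, calibration = collmigr::calibration(),
                        source_label = "") {
  if (!inherits(calibration, "calibration")) {
    stop("`calibration` must be a calibration object", call. = FALSE)
  }
  spots <- as.data.frame(spots)
  required <- c("spot_id", "track_id", "x", "y", "frame")
  missing_cols <- setdiff(required, names(spots))
  if (length(missing_cols)) {
    stop("spots is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  spots <- spots[required]
  if (nrow(spots)) {
    spots$spot_id <- as.integer(spots$spot_id)
    spots$track_id <- as.integer(spots$track_id)
    spots$frame <- as.integer(spots$frame)
    spots$x <- as.numeric(spots$x)
    spots$y <- as.numeric(spots$y)
    if (anyNA(spots$frame) || any(spots$frame < 0L)) {
      stop("`frame` must be a non-negative integer", call. = FALSE)
    }
    if (!all(is.finite(spots$x)) || !all(is.finite(spots$y))) {
      stop("positions must be finite", call. = FALSE)
    }
    dup <- duplicated(spots[c("track_id", "frame")])
    if (any(dup)) {
      first <- which(dup)[1L]
      stop(sprintf(
        "duplicate observation of track %d at frame %d: one observation of a nucleus per frame",
        spots$track_id[first], spots$frame[first]), call. = FALSE)
    }
    spots <- spots[order(spots$track_id, spots$frame), , drop = FALSE]
    rownames(spots) <- NULL
  }
  structure(spots,
            calibration = calibration,
            source_label = as.character(source_label)[1L],
            class = c("track_table", "data.frame"))
}

#' @export
print.track_table <- function(x, ...) {
  cal <- attr(x, "calibration")
  cat(sprintf("<track_table> %d spots, %d tracks, frames %s, source \"%s\"\n",
              nrow(x), length(unique(x$track_id)),
              if (nrow(x)) paste0(min(x$frame), "..", max(x$frame)) else "-",
              attr(x, "source_label")))
  cat(sprintf("  calibration: %g um/px, %g min/frame, fiber axis %g deg\n",
              cal$pixel_size, cal$frame_interval, cal$fiber_axis_deg))
  NextMethod()
}

#' Retrieve the calibration of a track table
#' @param table A `track_table`.
#' @return The [calibration()] object attached to `table`.
#' @export
track_calibration <- function(table) {
  cal <- attr(table, "calibration")
  if (is.null(cal)) stop("object has no calibration attribute", call. = FALSE)
  cal
}

# Delimiter sniffing on the header line: tab wins if present, else comma.
sniff_sep <- function(header_line) {
  if (grepl("\t", header_line, fixed = TRUE)) "\t" else ","
}

#' Read a tracker spot-statistics table
#'
#' Parses delimited spot-statistics exports (TrackMate style). The file
#' must contain columns matching `ID`, `TRACK_ID`, `POSITION_X`,
#' `POSITION_Y` and `FRAME` (case-insensitive; extra columns are
#' ignored; comma or tab separation is auto-detected from the header
#' row). Newer export dialects insert auxiliary unit/label rows directly
#' below the column header; any contiguous block of rows after the
#' header whose frame field is non-numeric is skipped. Rows with a
#' missing or non-numeric track ID (spots the upstream linker left
#' unassigned) are dropped and counted in the `n_unlinked_dropped`
#' attribute of the result.
#'
#' @param path Path to the delimited text file.
#' @param calibration A [calibration()] object; positions are multiplied
#'   by `pixel_size` when `unit = "pixel"`, and y is mirrored about the
#'   data midline when `flip_y` is set.
#' @param unit Unit of the positions in the file: `"um"` (already
#'   microns) or `"pixel"`.
#' @param source_label Label stored on the returned table.
#'
#' @return A [track_table()]; attribute `n_unlinked_dropped` reports how
#'   many unlinked spots were discarded.
#' @export
read_spot_table <- function(path, calibration = collmigr::calibration(),
                            unit = c("um", "pixel"), source_label = "") {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("format error: empty file: ", path, call. = FALSE)
  sep <- sniff_sep(lines[1L])
  raw <- utils::read.table(text = lines, sep = sep, header = TRUE,
                           colClasses = "character", quote = "\"",
                           check.names = FALSE, comment.char = "",
                           stringsAsFactors = FALSE)
  nm_upper <- toupper(trimws(names(raw)))
  wanted <- c(spot_id = "ID", track_id = "TRACK_ID",
              x = "POSITION_X", y = "POSITION_Y", frame = "FRAME")
  idx <- match(wanted, nm_upper)
  if (anyNA(idx)) {
    stop("format error: missing required column(s): ",
         paste(wanted[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  df <- raw[idx]
  names(df) <- names(wanted)

  # Skip the auxiliary metadata block of multi-header export dialects:
  # leading rows whose frame field does not parse as a number.
  if (nrow(df)) {
    frame_num <- suppressWarnings(as.numeric(df$frame))
    aux <- cumprod(is.na(frame_num)) == 1
    df <- df[!aux, , drop = FALSE]
  }
  if (nrow(df) == 0L) {
    stop("format error: no data rows in ", path, call. = FALSE)
  }

  track_num <- suppressWarnings(as.numeric(df$track_id))
  unlinked <- is.na(track_num)
  n_unlinked <- sum(unlinked)
  df <- df[!unlinked, , drop = FALSE]

  spots <- data.frame(
    spot_id = suppressWarnings(as.integer(as.numeric(df$spot_id))),
    track_id = as.integer(track_num[!unlinked]),
    x = suppressWarnings(as.numeric(df$x)),
    y = suppressWarnings(as.numeric(df$y)),
    frame = suppressWarnings(as.integer(as.numeric(df$frame)))
  )
  if (anyNA(spots$x) || anyNA(spots$y) || anyNA(spots$frame)) {
    stop("format error: non-numeric position or frame values in ", path,
         call. = FALSE)
  }
  dup <- duplicated(spots[c("track_id", "frame")])
  if (any(dup)) {
    first <- which(dup)[1L]
    stop(sprintf(
      "integrity error: duplicate (track_id=%d, frame=%d) in %s",
      spots$track_id[first], spots$frame[first], path), call. = FALSE)
  }
  if (unit == "pixel") {
    spots$x <- spots$x * calibration$pixel_size
    spots$y <- spots$y * calibration$pixel_size
  }
  if (isTRUE(calibration$flip_y) && nrow(spots)) {
    mid2 <- min(spots$y) + max(spots$y)  # mirror about the data midline
    spots$y <- mid2 - spots$y
  }
  out <- track_table(spots, calibration = calibration,
                     source_label = source_label)
  attr(out, "n_unlinked_dropped") <- n_unlinked
  out
}

#' Remove short or immotile tracks
#'
#' Programmatic stand-in for the manual removal of non-migrating dead
#' cells: tracks with fewer than `min_points` observations, or whose
#' accumulated path length falls below `min_accumulated_um`, are
#' dropped. The defaults remove only single-observation tracks, which
#' carry no displacement information.
#'
#' @param table A [track_table()].
#' @param min_points Minimum number of observations a track must have
#'   (at least 1).
#' @param min_accumulated_um Minimum accumulated path length in microns.
#'
#' @return The filtered `track_table`; attribute `removal_report` is a
#'   data.frame of `track_id` and `reason`
#'   (`"too_few_points"` / `"below_min_distance"`).
#' @export
filter_tracks <- function(table, min_points = 2L, min_accumulated_um = 0) {
  stopifnot(inherits(table, "track_table"))
  if (min_points < 1L) stop("`min_points` must be >= 1", call. = FALSE)
  if (min_accumulated_um < 0) stop("`min_accumulated_um` must be >= 0", call. = FALSE)

  report <- data.frame(track_id = integer(), reason = character())
  if (nrow(table)) {
    by_track <- split(table[c("x", "y", "frame")], table$track_id)
    ids <- as.integer(names(by_track))
    n_points <- vapply(by_track, nrow, integer(1))
    accum <- vapply(by_track, function(d) {
      if (nrow(d) < 2L) return(0)
      d <- d[order(d$frame), ]
      sum(sqrt(diff(d$x)^2 + diff(d$y)^2))
    }, numeric(1))
    too_few <- n_points < min_points
    too_short <- !too_few & accum < min_accumulated_um
    report <- data.frame(
      track_id = c(ids[too_few], ids[too_short]),
      reason = c(rep("too_few_points", sum(too_few)),
                 rep("below_min_distance", sum(too_short)))
    )
    keep_ids <- ids[!(too_few | too_short)]
    table <- table[table$track_id %in% keep_ids, , drop = FALSE]
    rownames(table) <- NULL
  }
  out <- track_table(as.data.frame(table),
                     calibration = attr(table, "calibration"),
                     source_label = attr(table, "source_label"))
  attr(out, "removal_report") <- report[order(report$track_id), , drop = FALSE]
  out
}

#' Write a result table as delimited text
#'
#' Writes any tabular result (spots, steps, per-track metrics, per-frame
#' series) as comma-separated text with a single header row. Floating
#' values keep full precision (at least 6 significant digits) so tables
#' round-trip through [read_result_table()]; `NaN`/`NA` are serialized
#' literally. List columns (e.g. per-frame ID sets) are joined with
#' `";"`.
#'
#' @param records A data.frame (or coercible).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  if (is.null(records)) stop("`records` must be non-null", call. = FALSE)
  df <- as.data.frame(records)
  for (j in seq_along(df)) {
    if (is.list(df[[j]])) {
      df[[j]] <- vapply(df[[j]], function(v) paste(v, collapse = ";"),
                        character(1))
    } else if (is.double(df[[j]]) && any(is.nan(df[[j]]))) {
      # write.table folds NaN into the NA string; serialize it literally
      # (as.character keeps 15 significant digits)
      df[[j]] <- as.character(df[[j]])
    }
  }
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("I/O error: cannot write ", path,
                                           call. = FALSE))
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read back a table written by [write_table()]
#'
#' @param path Path to a comma-separated file with a header row.
#' @return A data.frame.
#' @export
read_result_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
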