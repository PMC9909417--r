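# Deterministic raster overlay of classified nuclei. Rendering is pure
# arithmetic into an RGB array (no graphics device), so repeated runs are
# byte-identical and tests can probe exact pixel colours.

# 3x5 bitmap glyphs for the corner stamp (digits, F, T, dot, space).
.glyphs <- list(
  "0" = "111101101101111", "1" = "010110010010111", "2" = "111001111100111",
  "3" = "111001111001111", "4" = "101101111001001", "5" = "111100111001111",
  "6" = "111100111101111", "7" = "111001001010010", "8" = "111101111101111",
  "9" = "111101111001111", "F" = "111100110100100", "T" = "111010010010010",
  "." = "000000000000010", " " = "000000000000000"
)

# Stamp `text` into rgb array `img` (H x W x 3) at top-left offset, scale
# pixels per glyph cell.
stamp_text <- function(img, text, col = c(0, 0, 0), x0 = 4L, y0 = 4L,
                       scale = 2L) {
  chars <- strsplit(text, "")[[1L]]
  cx <- x0
  H <- dim(img)[1L]; W <- dim(img)[2L]
  for (ch in chars) {
    g <- .glyphs[[ch]]
    if (is.null(g)) g <- .glyphs[[" "]]
    bits <- as.integer(strsplit(g, "")[[1L]])
    for (row in 0:4) for (colm in 0:2) {
      if (bits[row * 3 + colm + 1L] == 1L) {
        ys <- y0 + row * scale + seq_len(scale) - 1L
        xs <- cx + colm * scale + seq_len(scale) - 1L
        ys <- ys[ys >= 1L & ys <= H]
        xs <- xs[xs >= 1L & xs <= W]
        for (k in 1:3) img[ys, xs, k] <- col[k]
      }
    }
    cx <- cx + 4L * scale
  }
  img
}

# Paint filled discs at integer pixel centres.
paint_discs <- function(img, px, py, radius, col) {
  H <- dim(img)[1L]; W <- dim(img)[2L]
  if (length(px) == 0L) return(img)
  offs <- expand.grid(dx = -radius:radius, dy = -radius:radius)
  offs <- offs[offs$dx^2 + offs$dy^2 <= radius^2, , drop = FALSE]
  for (i in seq_along(px)) {
    xs <- px[i] + offs$dx
    ys <- py[i] + offs$dy
    ok <- xs >= 1L & xs <= W & ys >= 1L & ys <= H
    for (k in 1:3) img[cbind(ys[ok], xs[ok], k)] <- col[k]
  }
  img
}

#' Render per-frame overlay images of classified nuclei
#'
#' Writes one PNG per frame with group nuclei in grey and single
#' (detached) nuclei in colour, the analogue of the overlay video used
#' to validate the dispersion threshold against phase-contrast footage.
#' The world-to-pixel mapping is fixed across frames (global bounding
#' box of all positions plus a margin) so motion is visually
#' comparable, and the frame index and threshold are stamped in the
#' top-left corner. Rendering is fully deterministic: the same table
#' produces byte-identical files.
#'
#' @param table A [track_table()].
#' @param classified Result of [classify_table()] for `table`.
#' @param out_dir Output directory (created if needed).
#' @param format `"png"` (lossless frame sequence). An animated-GIF
#'   container is not provided; assemble the sequence externally if a
#'   movie file is needed.
#' @param width Image width in pixels; height follows the aspect ratio.
#' @param margin_um Margin around the data bounding box, microns.
#' @param point_radius Nucleus disc radius in pixels.
#' @return Character vector of written file paths, invisibly.
#' @export
render_overlay <- function(table, classified, out_dir, format = c("png"),
                           width = 512L, margin_um = 20, point_radius = 3L) {
  format <- match.arg(format)
  stopifnot(inherits(table, "track_table"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  threshold <- attr(classified, "threshold")
  if (is.null(threshold)) threshold <- NA_real_

  # every time point in range gets an image; frames with no nuclei come
  # out blank apart from the stamp
  frames <- if (nrow(table)) seq(min(table$frame), max(table$frame)) else integer(0)
  col_bg <- c(1, 1, 1)
  col_group <- c(0.5, 0.5, 0.5)
  col_single <- c(0.84, 0.16, 0.16)

  if (nrow(table)) {
    xr <- range(table$x) + c(-1, 1) * margin_um
    yr <- range(table$y) + c(-1, 1) * margin_um
  } else {
    xr <- c(0, 1); yr <- c(0, 1)
  }
  scale <- (width - 1) / diff(xr)
  height <- max(32L, as.integer(ceiling(diff(yr) * scale)) + 1L)

  key_cls <- paste(classified$frame, classified$spot_id)
  paths <- character(length(frames))
  for (i in seq_along(frames)) {
    f <- frames[i]
    img <- array(rep(col_bg, each = height * width), dim = c(height, width, 3))
    sub <- table[table$frame == f, , drop = FALSE]
    if (nrow(sub)) {
      lab <- classified$label[match(paste(f, sub$spot_id), key_cls)]
      px <- as.integer(round((sub$x - xr[1L]) * scale)) + 1L
      py <- height - as.integer(round((sub$y - yr[1L]) * scale))  # y up
      img <- paint_discs(img, px[lab == "group"], py[lab == "group"],
                         point_radius, col_group)
      img <- paint_discs(img, px[lab == "single"], py[lab == "single"],
                         point_radius, col_single)
    }
    img <- stamp_text(img, sprintf("F %03d  T %g", f, threshold))
    paths[i] <- file.path(out_dir, sprintf("frame_%04d.png", f))
    png::writePNG(img, paths[i])
  }
  invisible(paths)
}
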