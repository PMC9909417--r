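#' Spatial and temporal calibration of a tracking experiment
#'
#' Bundles the constants needed to convert tracker output into physical
#' units: the pixel size, the acquisition cadence, the y-axis convention,
#' and the orientation of aligned fibers on the substrate (if any).
#'
#' `fiber_axis_deg` is an axial (nematic) quantity: a fiber oriented at
#' 110 degrees is the same fiber as one at -70 degrees. The value is
#' normalized into `(-90, 90]`. For aligned fiber mats imaged with fibers
#' running vertically, the conventional value is 90.
#'
#' @param pixel_size Microns per pixel; positive.
#' @param frame_interval Minutes per frame; positive.
#' @param flip_y If `TRUE`, positions read from file have their y
#'   coordinate mirrored about the data midline, converting the image
#'   convention (y increases downward) to the mathematical one (y
#'   increases upward). All distances and speeds are unaffected; angles
#'   change sign.
#' @param fiber_axis_deg Orientation of aligned fibers in degrees,
#'   normalized into `(-90, 90]`.
#'
#' @return An object of class `"calibration"`.
#' @examples
#' calibration(pixel_size = 0.65, frame_interval = 30, fiber_axis_deg = 90)
#' @export
calibration <- function(pixel_size = 1, frame_interval = 1,
                        flip_y = FALSE, fiber_axis_deg = 90) {
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      !is.finite(pixel_size) || pixel_size <= 0) {
    stop("`pixel_size` must be a single positive number (microns per pixel)",
         call. = FALSE)
  }
  if (!is.numeric(frame_interval) || length(frame_interval) != 1L ||
      !is.finite(frame_interval) || frame_interval <= 0) {
    stop("`frame_interval` must be a single positive number (minutes per frame)",
         call. = FALSE)
  }
  if (!is.logical(flip_y) || length(flip_y) != 1L || is.na(flip_y)) {
    stop("`flip_y` must be TRUE or FALSE", call. = FALSE)
  }
  if (!is.numeric(fiber_axis_deg) || length(fiber_axis_deg) != 1L ||
      !is.finite(fiber_axis_deg)) {
    stop("`fiber_axis_deg` must be a single finite number", call. = FALSE)
  }
  structure(
    list(
      pixel_size = as.numeric(pixel_size),
      frame_interval = as.numeric(frame_interval),
      flip_y = flip_y,
      fiber_axis_deg = normalize_axis_deg(fiber_axis_deg)
    ),
    class = "calibration"
  )
}

#' @export
print.calibration <- function(x, ...) {
  cat("<calibration>\n")
  cat(sprintf("  pixel size:     %g um/px\n", x$pixel_size))
  cat(sprintf("  frame interval: %g min\n", x$frame_interval))
  cat(sprintf("  flip y:         %s\n", x$flip_y))
  cat(sprintf("  fiber axis:     %g deg (axial)\n", x$fiber_axis_deg))
  invisible(x)
}

#' Normalize an angle in degrees into (-180, 180]
#'
#' @param a Numeric vector of angles in degrees.
#' @return Angles wrapped into the half-open interval `(-180, 180]`.
#' @export
normalize_angle_deg <- function(a) {
  a <- a %% 360
  a[a > 180] <- a[a > 180] - 360
  a
}

#' Normalize an axial orientation in degrees into (-90, 90]
#'
#' Axial quantities (fiber orientations) are defined modulo 180 degrees.
#'
#' @param a Numeric vector of orientations in degrees.
#' @return Orientations wrapped into `(-90, 90]`.
#' @export
normalize_axis_deg <- function(a) {
  a <- a %% 180
  a[a > 90] <- a[a > 90] - 180
  a
}
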