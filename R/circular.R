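#' Polar probability distribution of motion directions
#'
#' Bins direction angles into equal-width sectors covering the full
#' circle and returns per-bin probabilities. Angles are first normalized
#' into `(-180, 180]`; bins are half-open `[lo, hi)` with the final bin
#' closed at 180, so every angle lands in exactly one bin and results
#' are bit-reproducible.
#'
#' @param angles Numeric vector of direction angles in degrees.
#'   Undefined angles (`NA`, from zero-length steps) must be excluded by
#'   the caller.
#' @param n_bins Number of equal-width bins (at least 2).
#' @return An object of class `"polar_histogram"`: a list with
#'   `bin_edges_deg` (length `n_bins + 1`, spanning -180..180),
#'   `probabilities` (summing to 1, or all zero for empty input) and
#'   `n_angles`.
#' @examples
#' polar_distribution(c(90, 90, -90, -90), n_bins = 4)
#' @export
polar_distribution <- function(angles, n_bins = 24L) {
  if (!is.numeric(n_bins) || length(n_bins) != 1L || n_bins < 2L) {
    stop("`n_bins` must be a single integer >= 2", call. = FALSE)
  }
  n_bins <- as.integer(n_bins)
  angles <- angles[!is.na(angles)]
  if (any(!is.finite(angles))) stop("angles must be finite", call. = FALSE)
  edges <- seq(-180, 180, length.out = n_bins + 1L)
  width <- 360 / n_bins
  counts <- integer(n_bins)
  if (length(angles)) {
    a <- normalize_angle_deg(angles)
    idx <- floor((a + 180) / width) + 1L
    idx[idx > n_bins] <- n_bins  # 180 closes the final bin
    counts <- tabulate(idx, nbins = n_bins)
  }
  n <- length(angles)
  structure(
    list(bin_edges_deg = edges,
         probabilities = if (n) counts / n else rep(0, n_bins),
         n_angles = n),
    class = "polar_histogram"
  )
}

#' @export
print.polar_histogram <- function(x, ...) {
  cat(sprintf("<polar_histogram> %d bins, %d angles\n",
              length(x$probabilities), x$n_angles))
  invisible(x)
}

#' Nematic alignment order parameter
#'
#' Summarizes how concentrated a set of motion directions is about the
#' fiber axis, treating direction as axial (a step at theta and one at
#' theta + 180 are equally "along the fibers"):
#' \deqn{S = \langle \cos 2(\theta - \phi) \rangle}
#' with \eqn{\phi} the fiber axis. `S = 1` means all motion parallel to
#' the fibers, `S = 0` isotropic motion, `S = -1` all motion
#' perpendicular.
#'
#' @param angles Numeric vector of direction angles in degrees; `NA`
#'   entries (undefined directions) are dropped.
#' @param fiber_axis_deg Fiber axis orientation in degrees.
#' @return A number in `[-1, 1]`, or `NA` if no defined angle remains.
#' @export
alignment_order <- function(angles, fiber_axis_deg) {
  angles <- angles[!is.na(angles)]
  if (length(angles) == 0L) return(NA_real_)
  mean(cos(2 * (angles - fiber_axis_deg) * pi / 180))
}

# Best & Fisher (1979) rejection sampler for the von Mises distribution,
# in radians. Vectorized batch rejection; all candidate draws consume the
# RNG stream whether accepted or not, so output is reproducible.
rvonmises <- function(n, mu, kappa) {
  if (kappa < 0) stop("`kappa` must be >= 0", call. = FALSE)
  if (n == 0L) return(numeric())
  if (kappa < 1e-10) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(m)
    acc <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    u3 <- stats::runif(m)
    vals <- mu + sign(u3 - 0.5) * acos(pmin(pmax(f, -1), 1))
    k <- sum(acc)
    if (k) out[(got + 1L):(got + k)] <- vals[acc]
    got <- got + k
  }
  ((out + pi) %% (2 * pi)) - pi
}

#' Sample axial (nematic) von Mises directions
#'
#' Draws direction angles whose orientation is von Mises-concentrated
#' about an axis: the doubled angles `2 * theta` follow a von Mises
#' distribution with mean `2 * axis_deg` and concentration `kappa`, and
#' each draw receives an independent 180-degree flip, making the
#' distribution symmetric under `theta -> theta + 180`. This is the
#' standard model for contact guidance along fibers, which orient but do
#' not direct motion. `kappa = 0` reduces to the uniform distribution on
#' the circle. The expected [alignment_order()] about the axis is the
#' Bessel ratio `I1(kappa) / I0(kappa)`.
#'
#' @param n Number of draws (at least 1).
#' @param kappa Concentration parameter, `>= 0`.
#' @param axis_deg Axis orientation in degrees.
#' @return `n` angles in degrees in `(-180, 180]`.
#' @export
sample_axial_von_mises <- function(n, kappa, axis_deg) {
  if (!is.numeric(n) || length(n) != 1L || n < 1L) {
    stop("`n` must be a single integer >= 1", call. = FALSE)
  }
  if (!is.numeric(kappa) || length(kappa) != 1L || kappa < 0) {
    stop("`kappa` must be >= 0", call. = FALSE)
  }
  n <- as.integer(n)
  axis_rad <- axis_deg * pi / 180
  doubled <- if (kappa < 1e-10) {
    stats::runif(n, -pi, pi)
  } else {
    rvonmises(n, 2 * axis_rad, kappa)
  }
  # Halving the doubled angle covers only a half-circle about the axis;
  # the random flip restores the other, axially equivalent, half.
  theta <- if (kappa < 1e-10) axis_rad + doubled / 2 else {
    axis_rad + (((doubled - 2 * axis_rad + pi) %% (2 * pi)) - pi) / 2
  }
  flip <- stats::runif(n) < 0.5
  theta[flip] <- theta[flip] + pi
  normalize_angle_deg(theta * 180 / pi)
}
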