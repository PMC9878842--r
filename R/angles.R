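# Angle conventions and circular statistics.
#
# Global convention used everywhere in the package: angles in degrees,
# anterior = 0 deg, increasing counterclockwise in a right-handed frame
# (x to the right, y up). Image row index increases downward, so the row
# axis is negated whenever an angle is computed from pixel coordinates.
# Pixel coordinates are 0-based: x = column - 1, y = row - 1, and a pixel
# (r, c) has its center at (x + 0.5, y + 0.5).

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# wrap into [0, period), collapsing floating-point residue at the seam
wrap_angle <- function(x, period = 360) {
  y <- x %% period
  y[period - y < 1e-9] <- 0
  y
}

#' Angle of pixel positions about a center point
#'
#' Computes the angular position of pixel coordinates `(x, y)` about a center
#' `(cx, cy)` under the package angle convention (anterior = 0 degrees,
#' counterclockwise positive, screen y-axis negated).
#'
#' @param x,y Numeric vectors of pixel coordinates (0-based, x = column,
#'   y = row; y increases down the screen).
#' @param cx,cy Center of rotation in the same coordinate system.
#' @return Numeric vector of angles in degrees in `[0, 360)`.
#' @export
pixel_angle <- function(x, y, cx, cy) {
  wrap_angle(rad2deg(atan2(-(y - cy), x - cx)))
}

#' Minimal signed angular difference
#'
#' @param a,b Angles in degrees.
#' @param period Angular period: 360 for directions, 180 for axes.
#' @return Signed difference `a - b` wrapped into `(-period/2, period/2]`.
#' @export
angle_diff <- function(a, b, period = 360) {
  d <- (a - b) %% period
  ifelse(d > period / 2, d - period, d)
}

#' Circular mean and resultant length of directional data
#'
#' First trigonometric moment of a set of angles (360-degree period), as used
#' for rose-plot summaries of polarized follicle angles.
#'
#' @param angles_deg Angles in degrees.
#' @param w Optional non-negative weights.
#' @return A list with `mean_deg` (in `[0, 360)`) and `resultant` (mean
#'   resultant length in `[0, 1]`). Both are `NA` for empty input.
#' @export
circular_mean <- function(angles_deg, w = NULL) {
  if (length(angles_deg) == 0) {
    return(list(mean_deg = NA_real_, resultant = NA_real_))
  }
  if (is.null(w)) w <- rep(1, length(angles_deg))
  th <- deg2rad(angles_deg)
  C <- sum(w * cos(th)) / sum(w)
  S <- sum(w * sin(th)) / sum(w)
  list(mean_deg = wrap_angle(rad2deg(atan2(S, C))), resultant = sqrt(C^2 + S^2))
}

# Axial (180-degree periodic) mean: angles are doubled, averaged, halved.
# Used for nematic polarity aggregation; weights are per-cell magnitudes.
axial_mean <- function(axes_deg, w = NULL) {
  if (length(axes_deg) == 0) {
    return(list(mean_deg = NA_real_, resultant = NA_real_))
  }
  if (is.null(w)) w <- rep(1, length(axes_deg))
  th <- deg2rad(2 * axes_deg)
  C <- sum(w * cos(th)) / length(axes_deg)
  S <- sum(w * sin(th)) / length(axes_deg)
  list(mean_deg = wrap_angle(rad2deg(atan2(S, C)) / 2, 180),
       resultant = sqrt(C^2 + S^2))
}

#' Draw from the von Mises distribution
#'
#' Best–Fisher rejection sampler for the von Mises circular distribution,
#' used by the follicle simulator to disperse growth angles about a tissue
#' mean. Degenerate cases are handled explicitly: `kappa = 0` is the circular
#' uniform, and very large `kappa` (> 1e5) falls back to a wrapped normal
#' with sd `1/sqrt(kappa)` radians, which is indistinguishable at that
#' concentration.
#'
#' @param n Number of draws.
#' @param mu_deg Mean direction in degrees.
#' @param kappa Concentration parameter, `>= 0`.
#' @return Angles in degrees in `[0, 360)`.
#' @export
rvonmises <- function(n, mu_deg, kappa) {
  stopifnot(kappa >= 0, n >= 0)
  if (n == 0) return(numeric(0))
  if (kappa < 1e-8) return(stats::runif(n, 0, 360))
  if (kappa > 1e5) {
    return((mu_deg + rad2deg(stats::rnorm(n, 0, 1 / sqrt(kappa)))) %% 360)
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      i <- i + 1L
      out[i] <- sign(u3 - 0.5) * acos(pmin(pmax(f, -1), 1))
    }
  }
  (mu_deg + rad2deg(out)) %% 360
}

# Occupied-angular-bin coverage: number of bins of `bin_width` degrees that
# contain at least one angle, times the bin width. Degrees in [0, 360].
angular_coverage <- function(angles_deg, bin_width = 10) {
  if (length(angles_deg) == 0) return(0)
  nb <- ceiling(360 / bin_width)
  bins <- floor((angles_deg %% 360) / bin_width)
  bins[bins >= nb] <- nb - 1
  length(unique(bins)) * bin_width
}
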