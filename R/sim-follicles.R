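# Synthetic backskin: two-channel hair-follicle images with known polarity.

#' Simulate a two-channel hair-follicle image
#'
#' Generates a synthetic backskin field of view labelled for P-cadherin
#' (channel 1) and Sox9 (channel 2). Each follicle is a P-cadherin disc of
#' `core_radius` at its center. Unpolarized ("bicycle wheel") follicles carry
#' a full Sox9 annulus between `core_radius` and `follicle_radius`;
#' polarized follicles carry an annular Sox9 arc of `crescent_width` degrees
#' centered opposite the growth direction (at `theta + 180`), with the growth
#' angle `theta` drawn from a von Mises distribution. Signal is additive over
#' a constant background, with i.i.d. Gaussian noise.
#'
#' @param image_size Image size in pixels, `c(H, W)` or a single number.
#' @param n_follicles Number of follicles to place.
#' @param follicle_radius Outer follicle radius, pixels.
#' @param core_radius P-cadherin core radius, pixels; must be smaller than
#'   `follicle_radius`.
#' @param polarized_fraction Probability that a follicle is polarized.
#' @param angle_mean Mean growth angle, degrees (anterior = 0).
#' @param angle_concentration von Mises concentration kappa (`>= 0`).
#' @param crescent_width Angular width of the polarized Sox9 arc, degrees.
#' @param foreground_level Marker signal amplitude above background,
#'   intensity units.
#' @param noise_sd Gaussian noise sd, intensity units.
#' @param background_level Constant background, intensity units.
#' @param seed Integer RNG seed; the same seed reproduces the image exactly.
#' @return A list with `image` (`H x W x 2` array, channel 1 = P-cadherin,
#'   channel 2 = Sox9) and `truth`, a tibble with one row per follicle:
#'   `follicle_id`, `cx`, `cy` (0-based pixel coordinates of the center),
#'   `polarized`, `angle_deg` (NA when unpolarized).
#' @export
sim_follicle_image <- function(image_size = c(512, 512),
                               n_follicles = 20,
                               follicle_radius = 16,
                               core_radius = 6,
                               polarized_fraction = 0.7,
                               angle_mean = 0,
                               angle_concentration = 4,
                               crescent_width = 120,
                               foreground_level = 200,
                               noise_sd = 10,
                               background_level = 30,
                               seed = 1) {
  if (length(image_size) == 1) image_size <- c(image_size, image_size)
  stopifnot(
    core_radius < follicle_radius,
    polarized_fraction >= 0, polarized_fraction <= 1,
    crescent_width > 0, crescent_width < 360,
    noise_sd >= 0, n_follicles >= 1
  )
  H <- as.integer(image_size[1]); W <- as.integer(image_size[2])
  set.seed(as.integer(seed))

  centers <- place_follicle_centers(n_follicles, H, W, follicle_radius)
  polarized <- stats::runif(n_follicles) < polarized_fraction
  angles <- rep(NA_real_, n_follicles)
  if (any(polarized)) {
    angles[polarized] <- rvonmises(sum(polarized), angle_mean,
                                   angle_concentration)
  }

  pcad <- matrix(0, H, W)
  sox9 <- matrix(0, H, W)
  xg <- matrix(rep(seq_len(W) - 0.5, each = H), H, W)   # pixel-center x
  yg <- matrix(rep(seq_len(H) - 0.5, times = W), H, W)  # pixel-center y
  for (i in seq_len(n_follicles)) {
    cx <- centers[i, 1]; cy <- centers[i, 2]
    # restrict to a local window for speed
    r0 <- max(1L, floor(cy - follicle_radius)); r1 <- min(H, ceiling(cy + follicle_radius) + 1L)
    c0 <- max(1L, floor(cx - follicle_radius)); c1 <- min(W, ceiling(cx + follicle_radius) + 1L)
    dx <- xg[r0:r1, c0:c1] - cx
    dy <- yg[r0:r1, c0:c1] - cy
    d2 <- dx^2 + dy^2
    core <- d2 <= core_radius^2
    ann <- d2 > core_radius^2 & d2 <= follicle_radius^2
    if (polarized[i]) {
      phi <- rad2deg(atan2(-dy, dx)) %% 360
      arc_center <- (angles[i] + 180) %% 360
      ann <- ann & abs(angle_diff(phi, arc_center)) <= crescent_width / 2
    }
    blk <- pcad[r0:r1, c0:c1]; blk[core] <- foreground_level
    pcad[r0:r1, c0:c1] <- blk
    blk <- sox9[r0:r1, c0:c1]; blk[ann] <- foreground_level
    sox9[r0:r1, c0:c1] <- blk
  }

  img <- array(0, dim = c(H, W, 2))
  img[, , 1] <- background_level + pcad
  img[, , 2] <- background_level + sox9
  if (noise_sd > 0) {
    img <- img + array(stats::rnorm(length(img), 0, noise_sd), dim = dim(img))
  }

  truth <- tibble::tibble(
    follicle_id = seq_len(n_follicles),
    cx = centers[, 1], cy = centers[, 2],
    polarized = polarized,
    angle_deg = angles
  )
  list(image = img, truth = truth)
}

# Rejection-sample non-overlapping centers (center-to-center separation
# > 2 * follicle_radius, with a 3 px safety margin so annuli never touch).
place_follicle_centers <- function(n, H, W, radius, max_tries = 400L * n) {
  min_sep2 <- (2 * radius + 3)^2
  margin <- radius + 2
  if (H - 2 * margin <= 0 || W - 2 * margin <= 0) {
    stop("image too small for follicle radius ", radius)
  }
  centers <- matrix(NA_real_, n, 2)
  placed <- 0L
  for (t in seq_len(max_tries)) {
    cand <- c(stats::runif(1, margin, W - margin),
              stats::runif(1, margin, H - margin))
    if (placed > 0L) {
      d2 <- (centers[seq_len(placed), 1] - cand[1])^2 +
            (centers[seq_len(placed), 2] - cand[2])^2
      if (any(d2 <= min_sep2)) next
    }
    placed <- placed + 1L
    centers[placed, ] <- cand
    if (placed == n) return(centers)
  }
  stop("could not place ", n, " non-overlapping follicles of radius ", radius,
       " in a ", H, "x", W, " image after ", max_tries,
       " tries; reduce density (n * (2r)^2 should stay well below H*W)")
}
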