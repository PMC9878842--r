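# Synthetic cell-pair images for the junction-enrichment assay.

#' Simulate an adjacent cell pair with an enriched shared junction
#'
#' Two rectangular cell footprints share a vertical junction of
#' `junction_length` pixels in the image center. Membrane signal of
#' amplitude `membrane_intensity` (above background) is painted on a band of
#' `band_width` pixels along the outer periphery of the pair; the shared
#' junction band carries `enrichment_factor * membrane_intensity`. Signal is
#' additive over a constant background with Gaussian noise, mirroring a
#' membrane marker imaged in transfected cell pairs.
#'
#' ROI masks are returned alongside: the junction band, the cell-pair
#' periphery band (a contour-style ROI excluding the junction, i.e. the ROI
#' drawn "along the periphery of the two adjacent cells"), and a background
#' rectangle outside the pair.
#'
#' @param image_size Image side, pixels (square image).
#' @param junction_length Shared-junction length, pixels.
#' @param band_width Membrane/junction band width, pixels.
#' @param membrane_intensity Membrane signal amplitude, intensity units.
#' @param enrichment_factor True junction enrichment (`>= 0`).
#' @param background_level Constant background, intensity units.
#' @param noise_sd Gaussian noise sd.
#' @param seed Integer RNG seed.
#' @return A list with `image` (`H x W` matrix), `rois` (one-row tibble in
#'   [read_rois()] layout with logical mask list-columns) and `truth`
#'   (tibble: `enrichment_factor`, `membrane_intensity`,
#'   `background_level`).
#' @export
sim_cell_pair <- function(image_size = 120,
                          junction_length = 60,
                          band_width = 4,
                          membrane_intensity = 150,
                          enrichment_factor = 2,
                          background_level = 20,
                          noise_sd = 5,
                          seed = 1) {
  stopifnot(enrichment_factor >= 0, noise_sd >= 0, band_width >= 1,
            junction_length >= 4)
  H <- W <- as.integer(image_size)
  if (junction_length > H - 20) stop("junction_length too large for image")
  set.seed(as.integer(seed))

  xg <- matrix(rep(seq_len(W) - 0.5, each = H), H, W)
  yg <- matrix(rep(seq_len(H) - 0.5, times = W), H, W)

  # union footprint of the pair, centered; shared edge at x = xm
  hw <- band_width / 2
  cell_w <- round(W * 0.3)
  xm <- W / 2
  x0 <- xm - cell_w; x1 <- xm + cell_w
  y0 <- (H - junction_length) / 2; y1 <- y0 + junction_length

  # distance to the union-rectangle outline and to the shared edge
  inside <- xg >= x0 & xg <= x1 & yg >= y0 & yg <= y1
  d_edge <- pmin(abs(xg - x0), abs(xg - x1), abs(yg - y0), abs(yg - y1))
  near_rect <- d_edge <= hw &
    xg >= x0 - hw & xg <= x1 + hw & yg >= y0 - hw & yg <= y1 + hw
  perim <- near_rect & (inside | d_edge <= hw)
  junction <- abs(xg - xm) <= hw & yg >= y0 & yg <= y1
  perim <- perim & !junction

  img <- matrix(background_level, H, W)
  img[perim] <- background_level + membrane_intensity
  img[junction] <- background_level + enrichment_factor * membrane_intensity
  if (noise_sd > 0) {
    img <- img + matrix(stats::rnorm(H * W, 0, noise_sd), H, W)
  }

  bg_roi <- matrix(FALSE, H, W)
  bx <- max(2L, floor(x0 / 2) - 5L)
  bg_roi[2:min(H, 16), 2:max(3L, bx)] <- TRUE
  bg_roi <- bg_roi & !(xg >= x0 - hw - 1 & xg <= x1 + hw + 1 &
                       yg >= y0 - hw - 1 & yg <= y1 + hw + 1)

  rois <- tibble::tibble(
    image_ref = "pair",
    cell_style = "contour",
    junction = list(junction),
    cell = list(perim),
    background = list(bg_roi)
  )
  truth <- tibble::tibble(
    enrichment_factor = enrichment_factor,
    membrane_intensity = membrane_intensity,
    background_level = background_level
  )
  list(image = img, rois = rois, truth = truth)
}
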