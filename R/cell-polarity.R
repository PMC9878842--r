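# Per-cell nematic order of membrane fluorescence.
#
# The polarity of a membrane-localized protein in one cell is the
# intensity-weighted second circular moment of its boundary pixels about the
# cell centroid:
#
#   Q = sum_p I_p * exp(i * 2 * phi_p) / sum_p I_p
#
# magnitude = |Q| in [0, 1] (nematic order), axis = arg(Q) / 2 in [0, 180).
# Doubling the angle makes the measure axial: signal concentrated at phi and
# phi + 180 reinforces rather than cancels, which is the right symmetry for
# junctional enrichment along an axis.

#' Extract a cell's boundary band with angular positions
#'
#' Returns the pixels of the cell lying within `ring_width` of its outline
#' (the outline is the set of cell pixels with a 4-neighbor outside the
#' cell), together with each pixel's angular position about the cell
#' centroid under the package angle convention.
#'
#' @param labels Integer label image.
#' @param cell_id Cell label to extract; must exist in `labels`.
#' @param ring_width Band width in pixels (1 = outline only).
#' @param intensity Optional intensity image of the same shape; adds an
#'   `intensity` column.
#' @return Tibble of boundary pixels: `x`, `y` (0-based pixel centers),
#'   `phi_deg`, and `intensity` if supplied. Attribute `border_cell` is TRUE
#'   when the cell touches the image border.
#' @export
extract_boundary_pixels <- function(labels, cell_id, ring_width = 2,
                                    intensity = NULL) {
  mask <- labels == cell_id
  if (!any(mask)) stop("cell_id ", cell_id, " not present in label image")
  if (!is.null(intensity) && !all(dim(intensity) == dim(labels))) {
    stop("intensity and label images have different shapes")
  }
  H <- nrow(mask); W <- ncol(mask)

  pad_shift <- function(m, di, dj, fill = FALSE) {
    out <- matrix(fill, H, W)
    ri <- seq_len(H) + di; ci <- seq_len(W) + dj
    ok_r <- ri >= 1 & ri <= H; ok_c <- ci >= 1 & ci <= W
    out[ok_r, ok_c] <- m[ri[ok_r], ci[ok_c]]
    out
  }
  # outline: cell pixels with a 4-neighbor outside the cell (image edge
  # counts as outside)
  outside <- !mask
  outline <- mask & (pad_shift(outside, 1, 0, TRUE) |
                     pad_shift(outside, -1, 0, TRUE) |
                     pad_shift(outside, 0, 1, TRUE) |
                     pad_shift(outside, 0, -1, TRUE))
  band <- outline
  if (ring_width > 1) {
    for (k in seq_len(ring_width - 1)) {
      grown <- band
      for (di in -1:1) for (dj in -1:1) {
        if (di || dj) grown <- grown | pad_shift(band, di, dj)
      }
      band <- grown & mask
    }
  }

  idx <- which(mask, arr.ind = TRUE)
  cx <- mean(idx[, 2] - 0.5); cy <- mean(idx[, 1] - 0.5)
  bidx <- which(band, arr.ind = TRUE)
  out <- tibble::tibble(
    x = bidx[, 2] - 0.5,
    y = bidx[, 1] - 0.5,
    phi_deg = pixel_angle(bidx[, 2] - 0.5, bidx[, 1] - 0.5, cx, cy)
  )
  if (!is.null(intensity)) out$intensity <- intensity[band]
  attr(out, "border_cell") <- any(mask[1, ]) || any(mask[H, ]) ||
    any(mask[, 1]) || any(mask[, W])
  attr(out, "centroid") <- c(cx, cy)
  out
}

#' Nematic polarity of one pixel set
#'
#' Computes `Q = sum(I * exp(2i * phi)) / sum(I)` over boundary pixels and
#' reports its modulus (polarity magnitude, in `[0, 1]`) and half-argument
#' (polarity axis, degrees in `[0, 180)`).
#'
#' @param pixels Tibble with columns `phi_deg` and `intensity` (e.g. from
#'   [extract_boundary_pixels()]).
#' @param min_pixels Minimum number of pixels for a defined polarity.
#' @return One-row tibble: `axis_deg`, `magnitude`, `total_intensity`,
#'   `n_boundary_pixels`, `qc_flag` (`"ok"`, `"low_area"`, or
#'   `"no_signal"`; axis and magnitude are NA unless `"ok"`).
#' @export
compute_cell_polarity <- function(pixels, min_pixels = 8) {
  n <- nrow(pixels)
  tot <- sum(pixels$intensity)
  if (n < min_pixels) {
    return(tibble::tibble(axis_deg = NA_real_, magnitude = NA_real_,
                          total_intensity = tot, n_boundary_pixels = n,
                          qc_flag = "low_area"))
  }
  if (tot <= 0) {
    return(tibble::tibble(axis_deg = NA_real_, magnitude = NA_real_,
                          total_intensity = tot, n_boundary_pixels = n,
                          qc_flag = "no_signal"))
  }
  Q <- sum(pixels$intensity * exp(2i * deg2rad(pixels$phi_deg))) / tot
  tibble::tibble(
    axis_deg = wrap_angle(rad2deg(Arg(Q)) / 2, 180),
    magnitude = Mod(Q),
    total_intensity = tot,
    n_boundary_pixels = n,
    qc_flag = "ok"
  )
}

#' Per-cell polarity of a whole tissue
#'
#' Runs [extract_boundary_pixels()] + [compute_cell_polarity()] on every
#' cell of a label image. Cells touching the image border are flagged
#' `"border"` (they are excluded from tissue aggregates by default, since
#' their boundary band is truncated).
#'
#' @param labels Integer label image (0 = background, if present).
#' @param intensity Intensity image, same shape.
#' @param ring_width Boundary band width, pixels.
#' @param min_pixels Minimum boundary pixels per cell.
#' @return Tibble with one row per cell: `cell_id`, `axis_deg`, `magnitude`,
#'   `total_intensity`, `n_boundary_pixels`, `qc_flag`.
#' @export
cell_polarity <- function(labels, intensity, ring_width = 2, min_pixels = 8) {
  ids <- sort(setdiff(unique(as.vector(labels)), 0))
  purrr::map_dfr(ids, function(id) {
    px <- extract_boundary_pixels(labels, id, ring_width, intensity)
    res <- compute_cell_polarity(px, min_pixels)
    if (attr(px, "border_cell") && res$qc_flag == "ok") res$qc_flag <- "border"
    dplyr::bind_cols(tibble::tibble(cell_id = id), res)
  })
}

#' Aggregate per-cell polarity into a tissue summary
#'
#' The tissue-level polarity is the mean of the per-cell nematic vectors
#' `magnitude * exp(2i * axis)`: its modulus is the mean polarity magnitude
#' (coherence across cells) and its half-argument the mean axis. An axial
#' histogram of per-cell axes over `[0, 180)` is attached for circular
#' plotting.
#'
#' @param vectors Tibble from [cell_polarity()]; only `qc_flag == "ok"` rows
#'   (or `"border"` rows if `include_border = TRUE`) enter the aggregate.
#' @param bin_width Histogram bin width, degrees (default 15).
#' @param include_border Include border-truncated cells (default FALSE).
#' @return One-row tibble: `n_cells`, `mean_axis_deg`, `mean_magnitude`,
#'   and list-column `histogram` (`bin_start`, `bin_mid`, `count`).
#' @export
aggregate_polarity <- function(vectors, bin_width = 15,
                               include_border = FALSE) {
  keep <- vectors$qc_flag == "ok" |
    (include_border & vectors$qc_flag == "border")
  v <- vectors[keep & !is.na(vectors$magnitude), ]
  if (nrow(v) == 0) stop("no cells with defined polarity to aggregate")
  z <- mean(v$magnitude * exp(2i * deg2rad(v$axis_deg)))
  breaks <- seq(0, 180, by = bin_width)
  nb <- length(breaks) - 1
  cnt <- tabulate(pmin(floor((v$axis_deg %% 180) / bin_width) + 1, nb),
                  nbins = nb)
  hist <- tibble::tibble(
    bin_start = breaks[-length(breaks)],
    bin_mid = breaks[-length(breaks)] + bin_width / 2,
    count = cnt
  )
  tibble::tibble(
    n_cells = nrow(v),
    mean_axis_deg = wrap_angle(rad2deg(Arg(z)) / 2, 180),
    mean_magnitude = Mod(z),
    histogram = list(hist)
  )
}
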