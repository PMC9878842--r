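# Junction enrichment: background-corrected ratio of junction to cell-pair
# mean intensity, and distribution comparisons between conditions.

#' Background-correct an image using a background ROI
#'
#' Subtracts the mean intensity of the background ROI from every pixel.
#' Negative values are clipped at zero by default so downstream ROI means
#' stay interpretable; set `clip_negative = FALSE` for strictly linear
#' correction.
#'
#' @param image `H x W` matrix.
#' @param background_roi Logical mask of the same shape, non-empty.
#' @param clip_negative Clip negative corrected values at 0 (default TRUE).
#' @return List with `image` (corrected matrix) and `background_mean`.
#' @export
background_correct <- function(image, background_roi, clip_negative = TRUE) {
  if (!any(background_roi)) stop("background ROI is empty")
  if (!all(dim(image) == dim(background_roi))) {
    stop("image and background ROI have different shapes")
  }
  bg <- mean(image[background_roi])
  out <- image - bg
  if (clip_negative) out[out < 0] <- 0
  list(image = out, background_mean = bg)
}

#' Junction enrichment of one or more ROI sets
#'
#' For each ROI set, background-corrects the image with its background ROI
#' and reports `je = mean(junction ROI) / mean(cell ROI)`, both means taken
#' on the corrected image. The cell ROI may be a contour band along the
#' periphery of the cell pair or a filled footprint; the `cell_style` column
#' is carried through because the two conventions yield different expected
#' ratios.
#'
#' @param image `H x W` matrix, typically a maximum-intensity projection.
#' @param rois ROI-set tibble in [read_rois()] layout (list-columns
#'   `junction`, `cell`, `background` of logical masks).
#' @param clip_negative Passed to [background_correct()].
#' @return Tibble with one row per ROI set: `image_ref`, `cell_style`, `je`,
#'   `junction_mean`, `cell_mean`, `background_mean`, `qc_flag` (`"ok"`, or
#'   `"undefined"` when the corrected cell mean is not positive, with
#'   `je = NA`; `"junction_outside_cell"` warns when the junction ROI is not
#'   inside the cell footprint for filled-style ROIs).
#' @export
junction_enrichment <- function(image, rois, clip_negative = TRUE) {
  purrr::pmap_dfr(rois, function(image_ref, cell_style, junction, cell,
                                 background, ...) {
    if (!any(junction) || !any(cell)) stop("empty junction or cell ROI")
    corr <- background_correct(image, background, clip_negative)
    jm <- mean(corr$image[junction])
    cm <- mean(corr$image[cell])
    qc <- "ok"
    if (identical(cell_style, "filled") && any(junction & !cell)) {
      warning("junction ROI extends outside the cell ROI (", image_ref, ")")
      qc <- "junction_outside_cell"
    }
    if (cm <= 0) {
      return(tibble::tibble(
        image_ref = image_ref, cell_style = cell_style, je = NA_real_,
        junction_mean = jm, cell_mean = cm,
        background_mean = corr$background_mean, qc_flag = "undefined"
      ))
    }
    tibble::tibble(
      image_ref = image_ref, cell_style = cell_style, je = jm / cm,
      junction_mean = jm, cell_mean = cm,
      background_mean = corr$background_mean, qc_flag = qc
    )
  })
}

#' Compare two distributions of enrichment scores
#'
#' Two-sample Kolmogorov-Smirnov test: `D = sup |ECDF_a - ECDF_b|`, the
#' standard non-parametric comparison for junction-enrichment distributions.
#' The p-value uses the exact small-sample distribution when feasible
#' (stats::ks.test default) or the asymptotic one.
#'
#' @param scores_a,scores_b Numeric vectors, each of length `>= 2`.
#' @param exact Passed to [stats::ks.test()] (NULL = automatic).
#' @return One-row tibble: `statistic` (KS D), `p_value`, `n1`, `n2`.
#' @export
compare_groups <- function(scores_a, scores_b, exact = NULL) {
  if (length(scores_a) < 2 || length(scores_b) < 2) {
    stop("each group needs at least 2 scores")
  }
  kt <- suppressWarnings(stats::ks.test(scores_a, scores_b, exact = exact))
  tibble::tibble(
    statistic = unname(kt$statistic),
    p_value = kt$p.value,
    n1 = length(scores_a),
    n2 = length(scores_b)
  )
}
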