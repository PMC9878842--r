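# Hair-follicle polarity: segmentation of marker regions, polarized /
# non-polarized classification, growth angles, and tissue summaries.
#
# The biology behind the geometry: Sox9+ progenitors sit on the posterior
# side of a polarized follicle and P-cadherin-high cells on the anterior,
# so a polarized follicle shows a Sox9 crescent offset from the P-cadherin
# core, and the vector from the Sox9 centroid to the P-cadherin centroid
# points along the growth direction. An unpolarized follicle shows a
# concentric "bicycle wheel" Sox9 ring instead.

#' Segment follicle marker regions from a two-channel image
#'
#' Thresholds each channel (Otsu by default), extracts connected components,
#' drops components below `min_area`, and pairs every P-cadherin component
#' with the nearest Sox9 component within `pairing_radius`. Unpaired
#' components are reported with `qc_flag = "unpaired"` rather than silently
#' dropped; downstream classification uses only `qc_flag == "ok"` rows.
#'
#' @param image `H x W x 2` array; channel 1 = P-cadherin, channel 2 = Sox9.
#' @param min_area Minimum component area in pixels.
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param thresholds Numeric length-2 vector of per-channel thresholds,
#'   required when `threshold_method = "fixed"`.
#' @param pairing_radius Maximum centroid distance for pairing; default
#'   3 x the median equivalent radius (`sqrt(area / pi)`) of all components.
#' @return Tibble with one row per paired follicle (and one per unpaired
#'   component): `follicle_id`, `qc_flag`, `cx`, `cy` (union centroid,
#'   0-based pixel coordinates), `radius_est`, and list-columns
#'   `pcad_pixels`, `sox9_pixels` of `(x, y)` pixel-center tibbles.
#' @export
segment_follicles <- function(image,
                              min_area = 50,
                              threshold_method = c("otsu", "fixed"),
                              thresholds = NULL,
                              pairing_radius = NULL) {
  threshold_method <- match.arg(threshold_method)
  if (length(dim(image)) != 3 || dim(image)[3] != 2) {
    stop("expected a two-channel image (H x W x 2: P-cadherin, Sox9)")
  }
  comp <- purrr::map(1:2, function(ch) {
    x <- image[, , ch]
    thr <- if (threshold_method == "fixed") {
      if (is.null(thresholds) || length(thresholds) != 2) {
        stop("threshold_method = 'fixed' needs 'thresholds' of length 2")
      }
      thresholds[ch]
    } else {
      otsu_threshold(x)
    }
    label_components(x > thr, min_area)
  })
  pcad <- comp[[1]]; sox9 <- comp[[2]]
  if (nrow(pcad$stats) == 0 || nrow(sox9$stats) == 0) {
    warning("a channel is empty after thresholding; no follicles found")
    return(empty_segmentation())
  }

  if (is.null(pairing_radius)) {
    eq_r <- sqrt(c(pcad$stats$area, sox9$stats$area) / pi)
    pairing_radius <- 3 * stats::median(eq_r)
  }

  # pair each P-cad component with its nearest Sox9 centroid; a Sox9
  # component can serve only one follicle (nearer claim wins)
  np <- nrow(pcad$stats); ns <- nrow(sox9$stats)
  d <- outer(pcad$stats$cx, sox9$stats$cx, "-")^2 +
       outer(pcad$stats$cy, sox9$stats$cy, "-")^2
  d <- sqrt(d)
  pair <- rep(NA_integer_, np)
  ord <- order(apply(d, 1, min))
  taken <- rep(FALSE, ns)
  for (i in ord) {
    j <- which.min(ifelse(taken, Inf, d[i, ]))
    if (length(j) && is.finite(d[i, j]) && d[i, j] <= pairing_radius) {
      pair[i] <- j
      taken[j] <- TRUE
    }
  }

  rows <- list()
  fid <- 0L
  for (i in seq_len(np)) {
    if (is.na(pair[i])) next
    fid <- fid + 1L
    pp <- pcad$pixels[[i]]
    sp <- sox9$pixels[[pair[i]]]
    ux <- c(pp$x, sp$x); uy <- c(pp$y, sp$y)
    pc <- c(mean(pp$x), mean(pp$y))
    radius_est <- sqrt(max((sp$x - pc[1])^2 + (sp$y - pc[2])^2))
    rows[[length(rows) + 1]] <- tibble::tibble(
      follicle_id = fid, qc_flag = "ok",
      cx = mean(ux), cy = mean(uy), radius_est = radius_est,
      pcad_pixels = list(pp), sox9_pixels = list(sp)
    )
  }
  for (i in which(is.na(pair))) {
    fid <- fid + 1L
    pp <- pcad$pixels[[i]]
    rows[[length(rows) + 1]] <- tibble::tibble(
      follicle_id = fid, qc_flag = "unpaired",
      cx = pcad$stats$cx[i], cy = pcad$stats$cy[i], radius_est = NA_real_,
      pcad_pixels = list(pp), sox9_pixels = list(tibble::tibble(x = numeric(), y = numeric()))
    )
  }
  for (j in which(!taken)) {
    fid <- fid + 1L
    sp <- sox9$pixels[[j]]
    rows[[length(rows) + 1]] <- tibble::tibble(
      follicle_id = fid, qc_flag = "unpaired",
      cx = sox9$stats$cx[j], cy = sox9$stats$cy[j], radius_est = NA_real_,
      pcad_pixels = list(tibble::tibble(x = numeric(), y = numeric())),
      sox9_pixels = list(sp)
    )
  }
  dplyr::bind_rows(rows)
}

empty_segmentation <- function() {
  tibble::tibble(
    follicle_id = integer(), qc_flag = character(),
    cx = numeric(), cy = numeric(), radius_est = numeric(),
    pcad_pixels = list(), sox9_pixels = list()
  )
}

# Otsu threshold on the native intensity scale (EBImage works in [0, 1]).
otsu_threshold <- function(x) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(rng[2])  # flat image: nothing above threshold
  xn <- (x - rng[1]) / (rng[2] - rng[1])
  thr01 <- EBImage::otsu(EBImage::Image(xn), range = c(0, 1), levels = 256)
  rng[1] + thr01 * (rng[2] - rng[1])
}

# Connected components (8-connectivity) with per-component pixel lists and
# centroid/area stats; components under min_area are removed.
label_components <- function(mask, min_area) {
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- EBImage::imageData(lab)
  ids <- setdiff(unique(as.vector(lab)), 0)
  pixels <- list(); stats_rows <- list()
  for (id in ids) {
    idx <- which(lab == id, arr.ind = TRUE)
    if (nrow(idx) < min_area) next
    px <- tibble::tibble(x = idx[, 2] - 0.5, y = idx[, 1] - 0.5)
    pixels[[length(pixels) + 1]] <- px
    stats_rows[[length(stats_rows) + 1]] <- tibble::tibble(
      area = nrow(px), cx = mean(px$x), cy = mean(px$y)
    )
  }
  list(
    pixels = pixels,
    stats = if (length(stats_rows)) dplyr::bind_rows(stats_rows) else
      tibble::tibble(area = numeric(), cx = numeric(), cy = numeric())
  )
}

#' Classify follicles as polarized or non-polarized
#'
#' For each segmented follicle, measures (i) the angular coverage of Sox9
#' pixels about the P-cadherin centroid (occupied bins of `bin_width`
#' degrees) and (ii) the centroid offset ratio
#' `|centroid(Sox9) - centroid(P-cad)| / radius_est`. A follicle is called
#' non-polarized — the concentric "bicycle wheel" phenotype — when the Sox9
#' signal wraps nearly all the way around (`coverage >= ring_coverage_min`)
#' or sits concentric with the core (`offset_ratio < offset_ratio_min`).
#' Otherwise it is polarized, with growth angle the direction of the vector
#' from the Sox9 centroid to the P-cadherin centroid (anterior = 0 degrees).
#'
#' @param segs Segmentation tibble from [segment_follicles()].
#' @param ring_coverage_min Coverage (degrees) at and above which a follicle
#'   is a ring.
#' @param offset_ratio_min Offset ratio below which centroids are
#'   concentric.
#' @param bin_width Angular bin width (degrees) for the coverage measure.
#' @return Tibble of calls: `follicle_id`, `polarized`, `angle_deg` (NA when
#'   not polarized), `coverage_deg`, `offset_ratio`, `qc_flag`.
#' @export
classify_follicles <- function(segs,
                               ring_coverage_min = 300,
                               offset_ratio_min = 0.15,
                               bin_width = 10) {
  purrr::pmap_dfr(segs, function(follicle_id, qc_flag, cx, cy, radius_est,
                                 pcad_pixels, sox9_pixels, ...) {
    if (qc_flag != "ok") {
      return(tibble::tibble(
        follicle_id = follicle_id, polarized = NA, angle_deg = NA_real_,
        coverage_deg = NA_real_, offset_ratio = NA_real_, qc_flag = qc_flag
      ))
    }
    if (nrow(pcad_pixels) == 0 || nrow(sox9_pixels) == 0) {
      return(tibble::tibble(
        follicle_id = follicle_id, polarized = NA, angle_deg = NA_real_,
        coverage_deg = NA_real_, offset_ratio = NA_real_, qc_flag = "low_area"
      ))
    }
    pc <- c(mean(pcad_pixels$x), mean(pcad_pixels$y))
    sc <- c(mean(sox9_pixels$x), mean(sox9_pixels$y))
    phi <- pixel_angle(sox9_pixels$x, sox9_pixels$y, pc[1], pc[2])
    coverage <- angular_coverage(phi, bin_width)
    offset_ratio <- sqrt(sum((sc - pc)^2)) / radius_est
    non_pol <- coverage >= ring_coverage_min || offset_ratio < offset_ratio_min
    tibble::tibble(
      follicle_id = follicle_id,
      polarized = !non_pol,
      angle_deg = if (non_pol) NA_real_ else
        pixel_angle(pc[1], pc[2], sc[1], sc[2]),
      coverage_deg = coverage,
      offset_ratio = offset_ratio,
      qc_flag = "ok"
    )
  })
}

#' Summarize follicle polarity calls
#'
#' Computes the cumulative percentage of polarized follicles, the circular
#' mean and mean resultant length of polarized growth angles (first
#' trigonometric moment), and a rose-plot histogram of polarized angles.
#'
#' @param calls Tibble from [classify_follicles()]; rows with
#'   `qc_flag != "ok"` are excluded first.
#' @param bin_width Rose histogram bin width, degrees (default 20).
#' @return One-row tibble: `n_total`, `n_polarized`, `pct_polarized`,
#'   `circular_mean_deg` (NA when no follicle is polarized),
#'   `circular_resultant`, and a list-column `rose` holding the histogram
#'   tibble (`bin_start`, `bin_mid`, `count`; counts sum to `n_polarized`).
#' @export
summarize_calls <- function(calls, bin_width = 20) {
  ok <- dplyr::filter(calls, .data$qc_flag == "ok")
  if (nrow(ok) == 0) stop("no follicles with qc_flag == 'ok' to summarize")
  ang <- ok$angle_deg[ok$polarized]
  cm <- circular_mean(ang)
  breaks <- seq(0, 360, by = bin_width)
  nb <- length(breaks) - 1
  cnt <- if (length(ang)) {
    tabulate(pmin(floor((ang %% 360) / bin_width) + 1, nb), nbins = nb)
  } else {
    rep(0L, nb)
  }
  rose <- tibble::tibble(
    bin_start = breaks[-length(breaks)],
    bin_mid = breaks[-length(breaks)] + bin_width / 2,
    count = cnt
  )
  tibble::tibble(
    n_total = nrow(ok),
    n_polarized = sum(ok$polarized),
    pct_polarized = 100 * sum(ok$polarized) / nrow(ok),
    circular_mean_deg = cm$mean_deg,
    circular_resultant = cm$resultant,
    rose = list(rose)
  )
}
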