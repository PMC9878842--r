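# TIFF image I/O and stack helpers.
#
# Images are plain numeric matrices (rows = image rows, so the first index
# increases down the screen); multi-channel / multi-slice images are 3-d
# arrays with channels or slices along the third dimension. Intensities are
# kept in their native units (not rescaled to [0, 1]).

#' Read a TIFF image as a channel-indexed array
#'
#' Reads a single- or multi-page TIFF. Pages become the third dimension of
#' the returned array, so a two-channel follicle image reads as an
#' `H x W x 2` array. Integer TIFFs are returned in their original integer
#' units; float TIFFs as stored.
#'
#' @param path Path to a TIFF file.
#' @return Numeric array `H x W x C` (with `C = 1` for single-page files).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("TIFF pages have mismatched shapes: ", path)
  }
  pages <- lapply(pages, function(p) {
    bits <- attr(p, "bits.per.sample") %||% 16L
    scale <- if (bits == 8) 255 else 65535  # see write_image() convention
    if (length(dim(p)) == 3) p <- p[, , 1]  # collapse any within-page channels
    unclass(p) * scale
  })
  array(unlist(pages), dim = c(dims[1, 1], dims[2, 1], length(pages)))
}

#' Write an image array to a multi-page TIFF
#'
#' One page per channel/slice. Intensities are stored scaled by 1/65535
#' (the TIFF payload lives in `[0, 1]`); [read_image()] undoes the scaling,
#' so both functions work on the native intensity scale `[0, 65535]`.
#' `mode = "uint16"` rounds to 16-bit integers (the standard container for
#' label masks); `mode = "float32"` keeps fractional intensities to 32-bit
#' float precision. Values outside `[0, 65535]` are clipped.
#'
#' @param img Matrix or `H x W x C` array.
#' @param path Output path.
#' @param mode `"uint16"` or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, mode = c("uint16", "float32")) {
  mode <- match.arg(mode)
  if (length(dim(img)) == 2) img <- array(img, dim = c(dim(img), 1))
  pages <- lapply(seq_len(dim(img)[3]), function(k) img[, , k])
  if (mode == "uint16") {
    pages <- lapply(pages, function(p) pmin(pmax(round(p), 0), 65535) / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  } else {
    pages <- lapply(pages, function(p) pmin(pmax(p, 0), 65535) / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  }
  invisible(path)
}

#' Project an image stack to a single plane
#'
#' Average-intensity (AIP) or maximum-intensity (MIP) projection along the
#' third dimension. Follicle analysis conventionally runs on AIPs of the
#' confocal stack; junction-enrichment scoring on MIPs.
#'
#' @param stack `H x W x N` array.
#' @param method `"average"` or `"max"`.
#' @return `H x W` matrix.
#' @export
project_stack <- function(stack, method = c("average", "max")) {
  method <- match.arg(method)
  if (length(dim(stack)) == 2) return(stack)
  if (method == "average") {
    apply(stack, c(1, 2), mean)
  } else {
    apply(stack, c(1, 2), max)
  }
}

#' Rotate an image by a multiple of 90 degrees
#'
#' Rotation is counterclockwise in the package angle convention, i.e. a
#' feature at angle phi about the image center moves to `phi + 90 * k`.
#' Used in rotation-equivariance checks of the angle estimators.
#'
#' @param img Matrix or `H x W x C` array.
#' @param k Number of 90-degree increments (default 1).
#' @return Rotated image of the same type.
#' @export
rotate_image_90 <- function(img, k = 1) {
  k <- as.integer(k) %% 4L
  rot1 <- function(m) t(m[, ncol(m):1, drop = FALSE])
  rotk <- function(m) {
    for (i in seq_len(k)) m <- rot1(m)
    m
  }
  if (length(dim(img)) == 2) return(rotk(img))
  pages <- lapply(seq_len(dim(img)[3]), function(c) rotk(img[, , c]))
  array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
}
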