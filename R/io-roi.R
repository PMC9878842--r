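# ROI definitions: JSON polygons and mask TIFFs.
#
# Rasterization rule, used everywhere: pixel coordinates are 0-based with
# x = column and y = row; the pixel at (row r, col c) has its center at
# (c - 0.5, r - 0.5) in 1-based matrix indices. A polygon covers a pixel iff
# the pixel center lies inside under the even-odd rule with half-open edge
# handling (an edge at exactly the center's y or x belongs to the pixel on
# its high side). A unit-spaced axis-aligned rectangle [0,2]x[0,2] therefore
# covers exactly the 4 pixels whose centers are at 0.5 and 1.5.

#' Rasterize a polygon to a pixel mask
#'
#' Even-odd scanline fill with the package's half-open pixel-center rule.
#' Self-intersecting polygons are rejected.
#'
#' @param vertices Two-column matrix (or list of `[x, y]` pairs) of polygon
#'   vertices in 0-based pixel coordinates.
#' @param dim Image dimensions `c(H, W)`.
#' @return Logical `H x W` mask.
#' @export
rasterize_polygon <- function(vertices, dim) {
  if (is.list(vertices)) vertices <- do.call(rbind, lapply(vertices, as.numeric))
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2 || nrow(vertices) < 3) {
    stop("polygon needs >= 3 [x, y] vertices")
  }
  check_simple_polygon(vertices)
  H <- dim[1]; W <- dim[2]
  mask <- matrix(FALSE, H, W)
  xs <- vertices[, 1]; ys <- vertices[, 2]
  n <- nrow(vertices)
  x2 <- xs[c(2:n, 1)]; y2 <- ys[c(2:n, 1)]
  for (r in seq_len(H)) {
    yc <- r - 0.5
    lo <- pmin(ys, y2); hi <- pmax(ys, y2)
    hit <- which(lo <= yc & yc < hi)          # half-open in y
    if (length(hit) == 0) next
    xc <- xs[hit] + (yc - ys[hit]) * (x2[hit] - xs[hit]) / (y2[hit] - ys[hit])
    xc <- sort(xc)
    for (i in seq(1, length(xc) - 1, by = 2)) {
      cmin <- max(1L, ceiling(xc[i] + 0.5))
      cmax <- min(W, ceiling(xc[i + 1] + 0.5) - 1)
      if (cmin <= cmax) mask[r, cmin:cmax] <- TRUE
    }
  }
  mask
}

# Error (naming the offending vertex) if any two non-adjacent edges cross.
check_simple_polygon <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1), , drop = FALSE])
  cross <- function(ax, ay, bx, by) ax * by - ay * bx
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in seq(i + 2, jmax)) {
      p <- seg[i, 1:2]; r <- seg[i, 3:4] - p
      q <- seg[j, 1:2]; s <- seg[j, 3:4] - q
      d <- cross(r[1], r[2], s[1], s[2])
      if (abs(d) < 1e-12) next
      t <- cross(q[1] - p[1], q[2] - p[2], s[1], s[2]) / d
      u <- cross(q[1] - p[1], q[2] - p[2], r[1], r[2]) / d
      if (t > 1e-9 && t < 1 - 1e-9 && u > 1e-9 && u < 1 - 1e-9) {
        stop("self-intersecting polygon: edge starting at vertex ", i,
             " crosses edge starting at vertex ", j)
      }
    }
  }
  invisible(TRUE)
}

#' Read ROI sets from a JSON file
#'
#' The JSON is an array of ROI-set objects. Each object has an optional
#' `image_ref` string and `junction`, `cell`, `background` entries; each
#' entry is either `{"polygon": [[x, y], ...]}` (0-based pixel coordinates,
#' rasterized under the half-open pixel-center rule) or
#' `{"mask": "file.tif"}` (a mask TIFF, nonzero = in ROI, resolved relative
#' to the JSON file). The `cell` entry may carry `"style": "contour"` or
#' `"filled"`; this is propagated to junction-enrichment output.
#'
#' @param path Path to the ROI JSON file.
#' @param dim Image dimensions `c(H, W)` used to rasterize polygons.
#' @return A tibble with one row per ROI set: `image_ref`, `cell_style`, and
#'   list-columns `junction`, `cell`, `background` of logical masks.
#' @export
read_rois <- function(path, dim) {
  spec <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (length(spec) == 0) {
    return(tibble::tibble(
      image_ref = character(), cell_style = character(),
      junction = list(), cell = list(), background = list()
    ))
  }
  parse_roi <- function(entry) {
    if (!is.null(entry$polygon)) {
      rasterize_polygon(entry$polygon, dim)
    } else if (!is.null(entry$mask)) {
      m <- read_image(file.path(dirname(path), entry$mask))[, , 1]
      if (!all(dim(m) == dim)) stop("ROI mask shape mismatch: ", entry$mask)
      m != 0
    } else {
      stop("ROI entry needs 'polygon' or 'mask'")
    }
  }
  purrr::map_dfr(spec, function(s) {
    tibble::tibble(
      image_ref = s$image_ref %||% NA_character_,
      cell_style = s$cell$style %||% "filled",
      junction = list(parse_roi(s$junction)),
      cell = list(parse_roi(s$cell)),
      background = list(parse_roi(s$background))
    )
  })
}

#' Write ROI sets to JSON
#'
#' Inverse of [read_rois()] for mask-based ROI sets: masks are written as
#' uint16 TIFFs beside the JSON and referenced by filename.
#'
#' @param rois Tibble as returned by [read_rois()] or a simulator.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_rois <- function(rois, path) {
  dir <- dirname(path)
  spec <- purrr::pmap(rois, function(image_ref, cell_style, junction, cell,
                                     background, ...) {
    base <- paste0("roi_", gsub("[^A-Za-z0-9]", "_", image_ref %||% "set"))
    files <- list(junction = junction, cell = cell, background = background)
    entries <- purrr::imap(files, function(mask, nm) {
      f <- paste0(base, "_", nm, ".tif")
      write_image(mask * 1L, file.path(dir, f), mode = "uint16")
      list(mask = f)
    })
    entries$cell$style <- cell_style
    c(list(image_ref = image_ref), entries)
  })
  jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
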