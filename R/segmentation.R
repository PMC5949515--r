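#' Otsu threshold ("dark" polarity, ImageJ-style binning)
#'
#' Computes the threshold maximizing between-class variance on a 256-bin
#' histogram of the in-ROI pixels, the bins spanning the in-ROI min-max range
#' linearly. "Dark" polarity means the foreground is the bright class: pixels
#' strictly above the returned threshold. Ties in the variance criterion are
#' broken toward the lowest qualifying threshold.
#'
#' @param channel Numeric intensity matrix.
#' @param roi Optional logical mask restricting the histogram.
#' @param n_bins Histogram bin count (256, the 8-bit convention).
#' @return Threshold on the intensity scale of `channel`.
#' @export
otsu_threshold <- function(channel, roi = NULL, n_bins = 256L) {
  px <- if (is.null(roi)) as.numeric(channel) else as.numeric(channel[roi])
  if (length(px) == 0L) stop("empty ROI", call. = FALSE)
  rng <- range(px)
  if (rng[1] == rng[2]) {
    stop("constant image/ROI: no Otsu threshold exists", call. = FALSE)
  }
  bw <- (rng[2] - rng[1]) / n_bins
  idx <- pmin(floor((px - rng[1]) / bw), n_bins - 1)
  h <- as.numeric(tabulate(idx + 1L, nbins = n_bins))
  mids <- rng[1] + (seq_len(n_bins) - 0.5) * bw
  w <- cumsum(h)
  s <- cumsum(h * mids)
  k <- seq_len(n_bins - 1L)
  w0 <- w[k]; w1 <- w[n_bins] - w0
  valid <- w0 > 0 & w1 > 0
  mu0 <- s[k] / w0
  mu1 <- (s[n_bins] - s[k]) / w1
  bcv <- ifelse(valid, w0 * w1 * (mu0 - mu1)^2, -Inf)
  k_best <- which.max(bcv)  # first maximum = lowest qualifying threshold
  rng[1] + k_best * bw      # upper edge of the last background bin
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so labels that touch
# only diagonally are merged with a union-find pass over the two diagonal
# neighbour shifts.
#' @keywords internal
label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1L)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n_lab <- max(lab)
  if (n_lab < 2L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]
  a2 <- lab[-1, -nc];  b2 <- lab[-nr, -1]
  s1 <- a1 > 0L & b1 > 0L & a1 != b1
  s2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- unique(rbind(cbind(a1[s1], b1[s1]), cbind(a2[s2], b2[s2])))
  if (nrow(pairs) > 0L) {
    parent <- seq_len(n_lab)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    for (r in seq_len(nrow(pairs))) {
      ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    roots <- vapply(seq_len(n_lab), find, integer(1))
    relab <- match(roots, sort(unique(roots)))
    nz <- lab > 0L
    lab[nz] <- relab[lab[nz]]
  }
  lab
}

#' Binary morphology chain with particle analysis
#'
#' Applies the automated morphological chain to a thresholded mask: dilation
#' (disk of radius `radius` px), hole filling, erosion (same disk), 8-connected
#' component labeling, then particle analysis retaining objects with
#' `min_area_um2 <= area <= max_area_um2`. The symmetric single
#' dilation/erosion closes sub-2 px gaps and fills lumina while leaving
#' isolated object areas nearly unchanged. `radius = 0` reduces to plain
#' connected-component labeling.
#'
#' @param mask Logical (or 0/1) matrix.
#' @param pixel_size_um Pixel size, micrometers.
#' @param min_area_um2,max_area_um2 Area filter in square micrometers.
#' @param radius Structuring-element disk radius in pixels.
#' @return An `ist_objects` list: `labels` (integer matrix, labels contiguous
#'   from 1) and `objects`, a tibble with `id`, `area_px`, `area_um2`,
#'   0-based centroid `(x, y)`, bounding box and `touches_border`.
#' @export
morph_chain_label <- function(mask, pixel_size_um, min_area_um2 = 5,
                              max_area_um2 = 300, radius = 1L) {
  if (min_area_um2 >= max_area_um2) {
    stop("min_area_um2 must be < max_area_um2", call. = FALSE)
  }
  m <- (mask > 0) * 1L
  if (radius > 0L) {
    brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
    m <- EBImage::dilate(m, brush)
    m <- EBImage::fillHull(m)
    m <- EBImage::erode(m, brush)
  } else {
    m <- EBImage::fillHull(m)
  }
  lab <- label8(m > 0)
  n_lab <- max(lab)
  empty <- tibble::tibble(
    id = integer(), area_px = integer(), area_um2 = numeric(),
    x = numeric(), y = numeric(), xmin = integer(), xmax = integer(),
    ymin = integer(), ymax = integer(), touches_border = logical())
  if (n_lab == 0L) {
    return(structure(list(labels = lab, objects = empty,
                          pixel_size_um = pixel_size_um),
                     class = "ist_objects"))
  }
  nr <- nrow(lab)
  idx <- which(lab > 0L)
  l <- lab[idx]
  row0 <- (idx - 1L) %% nr          # 0-based y
  col0 <- (idx - 1L) %/% nr         # 0-based x
  area_px <- tabulate(l, nbins = n_lab)
  cx <- rowsum(col0, l)[, 1] / area_px
  cy <- rowsum(row0, l)[, 1] / area_px
  xmin <- vapply(split(col0, l), min, numeric(1))
  xmax <- vapply(split(col0, l), max, numeric(1))
  ymin <- vapply(split(row0, l), min, numeric(1))
  ymax <- vapply(split(row0, l), max, numeric(1))
  obj <- tibble::tibble(
    id = seq_len(n_lab), area_px = area_px,
    area_um2 = area_px * pixel_size_um^2,
    x = cx, y = cy,
    xmin = as.integer(xmin), xmax = as.integer(xmax),
    ymin = as.integer(ymin), ymax = as.integer(ymax),
    touches_border = xmin == 0 | ymin == 0 |
      xmax == ncol(lab) - 1L | ymax == nr - 1L)
  keep <- obj$area_um2 >= min_area_um2 & obj$area_um2 <= max_area_um2
  obj <- obj[keep, , drop = FALSE]
  relab <- integer(n_lab)
  relab[obj$id] <- seq_len(nrow(obj))
  nz <- lab > 0L
  lab[nz] <- relab[lab[nz]]
  obj$id <- seq_len(nrow(obj))
  structure(list(labels = lab, objects = obj, pixel_size_um = pixel_size_um),
            class = "ist_objects")
}

#' @export
print.ist_objects <- function(x, ...) {
  cat(sprintf("<ist_objects> %d object(s), %d x %d px label image\n",
              nrow(x$objects), nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Detect lectin-positive microvessels and compute their density
#'
#' Runs the full capillary detection chain on a field: Otsu threshold on the
#' whole FITC channel, the dilate/fill/erode/label chain, and the capillary
#' area filter (large-vessel rings fill to discs far above the area cap and
#' are excluded). Density is the retained object count divided by field area.
#'
#' A field with no lectin-positive structures has a unimodal FITC histogram;
#' there Otsu would split the tissue noise in half. Detection therefore
#' requires a minimum foreground/background mean-intensity contrast
#' (`min_contrast`, default 2.5; lectin is several-fold brighter than tissue
#' autofluorescence) and reports zero vessels when the split does not reach
#' it.
#'
#' @param field An [ist_field()].
#' @param config An [pipeline_config()].
#' @param min_contrast Minimum mean(foreground)/mean(background) ratio for
#'   the Otsu split to count as lectin detection.
#' @return List with `objects` (an `ist_objects`), `density` (counts/mm^2)
#'   and `threshold`.
#' @export
detect_microvessels <- function(field, config = pipeline_config(),
                                min_contrast = 2.5) {
  stopifnot(inherits(field, "ist_field"))
  constant <- min(field$fitc) == max(field$fitc)
  thr <- if (constant) NA_real_ else otsu_threshold(field$fitc)
  mask <- if (constant) matrix(FALSE, nrow(field$fitc), ncol(field$fitc))
          else field$fitc > thr
  contrast_ok <- any(mask) && !all(mask) &&
    mean(field$fitc[mask]) >= min_contrast * mean(field$fitc[!mask])
  if (!contrast_ok) {
    obj <- morph_chain_label(matrix(FALSE, nrow(field$fitc), ncol(field$fitc)),
                             field$pixel_size_um,
                             config$min_area_um2, config$max_area_um2,
                             radius = config$morph_radius)
    return(list(objects = obj, density = 0, threshold = thr))
  }
  obj <- morph_chain_label(mask, field$pixel_size_um,
                           config$min_area_um2, config$max_area_um2,
                           radius = config$morph_radius)
  list(objects = obj,
       density = nrow(obj$objects) / field_area_mm2(field),
       threshold = thr)
}

#' Rasterize a polygon ROI to a logical mask
#'
#' @param polygon n x 2 matrix of 0-based `(x, y)` pixel vertices (>= 3).
#' @param dim Image dimensions `c(nrow, ncol)`.
#' @return Logical matrix, `TRUE` for pixel centers inside the polygon.
#' @export
polygon_mask <- function(polygon, dim) {
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3L) {
    stop("ROI polygon needs at least 3 vertices", call. = FALSE)
  }
  if (min(polygon) < -0.5 || max(polygon[, 1]) > dim[2] - 0.5 ||
      max(polygon[, 2]) > dim[1] - 0.5) {
    stop("ROI polygon extends outside the image bounds", call. = FALSE)
  }
  mask <- matrix(FALSE, dim[1], dim[2])
  rows <- max(1L, floor(min(polygon[, 2])) + 1L):
    min(dim[1], ceiling(max(polygon[, 2])) + 1L)
  cols <- max(1L, floor(min(polygon[, 1])) + 1L):
    min(dim[2], ceiling(max(polygon[, 1])) + 1L)
  bnd <- rbind(polygon, polygon[1, ])
  grid <- cbind(rep(cols - 1L, each = length(rows)),
                rep(rows - 1L, times = length(cols)))
  inside <- mgcv::in.out(bnd, grid)
  mask[rows, cols] <- matrix(inside, nrow = length(rows))
  mask
}

#' Segment the endothelial ring of one large vessel
#'
#' Discards everything outside the vessel ROI, computes Otsu on the in-ROI
#' FITC pixels, and returns the in-ROI bright (lectin-positive) class -- the
#' endothelial ring -- as a mask ready to be transferred onto the Cy3 channel.
#'
#' @param field An [ist_field()].
#' @param roi Polygon matrix (0-based `(x, y)` vertices) or a one-row slice of
#'   a [vessel_rois()] tibble.
#' @param min_ring_area_um2 Sanity floor; a smaller segmented ring triggers a
#'   warning (the ROI likely missed the vessel).
#' @return Logical ring mask (same dimensions as the field).
#' @export
segment_endothelial_ring <- function(field, roi, min_ring_area_um2 = 50) {
  stopifnot(inherits(field, "ist_field"))
  if (is.data.frame(roi)) roi <- roi$polygon[[1]]
  inside <- polygon_mask(roi, dim(field$fitc))
  thr <- otsu_threshold(field$fitc, roi = inside)
  mask <- inside & field$fitc > thr
  area <- sum(mask) * field$pixel_size_um^2
  if (area < min_ring_area_um2) {
    warning(sprintf(
      "segmented ring area %.1f um^2 is below the sanity floor %.1f um^2; ROI may not contain a vessel",
      area, min_ring_area_um2), call. = FALSE)
  }
  mask
}

#' Equivalent-circle radius of a vessel from its ring mask
#'
#' Fills the ring's lumen and reports the equivalent-circle radius of the
#' filled outer contour, `sqrt(area / pi) * pixel_size`.
#'
#' @param ring_mask Logical mask of one connected ring or disc.
#' @param pixel_size_um Pixel size, micrometers.
#' @return Radius in micrometers.
#' @export
estimate_vessel_radius <- function(ring_mask, pixel_size_um) {
  if (!any(ring_mask)) stop("empty ring mask", call. = FALSE)
  filled <- EBImage::fillHull((ring_mask > 0) * 1L)
  sqrt(sum(filled > 0) / pi) * pixel_size_um
}
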