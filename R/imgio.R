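#' Pipeline configuration
#'
#' Central knob set for the analysis pipeline. Defaults follow the imaging
#' protocol being emulated where it states a value (Otsu "dark" polarity,
#' alpha = 0.05) and the package's documented choices elsewhere (disk radius
#' 1 px for the symmetric dilate/erode, capillary particle filter 5-300 um^2).
#'
#' @param channel_order Page order of the multi-page TIFFs.
#' @param otsu_polarity Only `"dark"` is supported: foreground is the bright
#'   class, pixels strictly above the threshold.
#' @param morph_radius Structuring-element disk radius (px) for the
#'   dilate/fill/erode chain; must be >= 1 here (the function itself also
#'   accepts 0 for plain labeling).
#' @param min_area_um2,max_area_um2 Particle-analysis area filter for
#'   capillaries; large-vessel rings fall above `max_area_um2` once
#'   hole-filled and are thereby excluded from the capillary count.
#' @param min_ring_area_um2 Sanity floor for a segmented endothelial ring;
#'   smaller rings flag the score record.
#' @param alpha Significance level.
#' @param posthoc_adjust Multiplicity adjustment for Dunn post hoc p-values
#'   (`"bonferroni"` or `"none"`).
#' @param extra_area_norm Additionally divide large-vessel endothelium scores
#'   by ring area (the mean-within-mask already accounts for area; off by
#'   default).
#' @param output_dir Optional default output directory for the drivers.
#' @return A list of class `ist_config`.
#' @export
pipeline_config <- function(channel_order = c("hoechst", "fitc", "cy3"),
                            otsu_polarity = "dark",
                            morph_radius = 1L,
                            min_area_um2 = 5,
                            max_area_um2 = 300,
                            min_ring_area_um2 = 50,
                            alpha = 0.05,
                            posthoc_adjust = c("bonferroni", "none"),
                            extra_area_norm = FALSE,
                            output_dir = NULL) {
  posthoc_adjust <- match.arg(posthoc_adjust)
  if (!identical(sort(channel_order), sort(c("hoechst", "fitc", "cy3")))) {
    stop("channel_order must be a permutation of hoechst, fitc, cy3",
         call. = FALSE)
  }
  if (otsu_polarity != "dark") {
    stop("only 'dark' Otsu polarity is supported", call. = FALSE)
  }
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0,1)", call. = FALSE)
  if (morph_radius < 1) stop("morph_radius must be >= 1 px", call. = FALSE)
  if (min_area_um2 >= max_area_um2) {
    stop("min_area_um2 must be < max_area_um2", call. = FALSE)
  }
  structure(list(
    channel_order = channel_order, otsu_polarity = otsu_polarity,
    morph_radius = as.integer(morph_radius),
    min_area_um2 = min_area_um2, max_area_um2 = max_area_um2,
    min_ring_area_um2 = min_ring_area_um2, alpha = alpha,
    posthoc_adjust = posthoc_adjust,
    extra_area_norm = isTRUE(extra_area_norm), output_dir = output_dir
  ), class = "ist_config")
}

#' Write a field as a multi-page 16-bit TIFF
#'
#' Pages are written in `channel_order` (default Hoechst, FITC, Cy3),
#' losslessly (deflate), with the pixel size stored in the TIFF
#' XResolution/YResolution/ResolutionUnit tags (pixels per centimeter).
#' Round-trips bit-exactly through [read_field()].
#'
#' @param field An [ist_field()].
#' @param path Output path; the parent directory is created if needed.
#' @param channel_order Page order.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path,
                        channel_order = c("hoechst", "fitc", "cy3")) {
  stopifnot(inherits(field, "ist_field"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  pages <- lapply(channel_order, function(ch) {
    m <- field[[ch]]
    if (max(m) > 65535) {
      warning("channel '", ch, "' saturates 16 bits; clipping", call. = FALSE)
      m <- pmin(m, 65535L)
    }
    m / 65535
  })
  ok <- tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                        compression = "deflate", reduce = FALSE)
  if (ok != length(pages)) stop("failed to write TIFF: ", path, call. = FALSE)
  tiff_set_resolution(path, field$pixel_size_um)
  invisible(path)
}

#' Read a field from a multi-page 16-bit TIFF
#'
#' @param path Path to a 3-page TIFF.
#' @param pixel_size_override Pixel size in micrometers, used when the file
#'   carries no resolution tags (and taking precedence when it does).
#' @param channel_order Page order used at write time.
#' @param genotype,age_months,mouse_id,slice_id,region Optional provenance
#'   (usually supplied from the manifest).
#' @return An [ist_field()].
#' @export
read_field <- function(path, pixel_size_override = NULL,
                       channel_order = c("hoechst", "fitc", "cy3"),
                       genotype = NA, age_months = NA, mouse_id = NA,
                       slice_id = NA, region = NA) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE)
  if (length(pages) != 3L) {
    stop("expected a 3-page TIFF (Hoechst/FITC/Cy3), got ", length(pages),
         " page(s): ", path, call. = FALSE)
  }
  ps <- pixel_size_override
  if (is.null(ps)) {
    xres <- attr(pages[[1]], "x.resolution")
    unit <- attr(pages[[1]], "resolution.unit")
    if (is.null(xres) || is.null(unit)) {
      stop("TIFF carries no resolution tags and no pixel_size_override ",
           "was given: ", path, call. = FALSE)
    }
    per_cm <- switch(as.character(unit),
                     cm = xres,
                     inch = xres / 2.54,
                     stop("unsupported TIFF resolution unit '", unit, "': ",
                          path, call. = FALSE))
    ps <- 10000 / per_cm
  }
  chans <- stats::setNames(pages, channel_order)
  ist_field(chans$hoechst, chans$fitc, chans$cy3, ps,
            genotype = genotype, age_months = age_months,
            mouse_id = mouse_id, slice_id = slice_id, region = region)
}

#' Load and validate a cohort manifest
#'
#' @param path CSV with columns `field_id`, `path`, `genotype`, `age_months`,
#'   `mouse_id`, `slice_id`, `region`, `pixel_size_um`.
#' @param check_paths Verify that each referenced image file exists.
#' @return A validated tibble (possibly zero rows).
#' @export
load_manifest <- function(path, check_paths = TRUE) {
  man <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           field_id = readr::col_character(),
                           path = readr::col_character(),
                           genotype = readr::col_character(),
                           age_months = readr::col_integer(),
                           mouse_id = readr::col_character(),
                           slice_id = readr::col_character(),
                           region = readr::col_character(),
                           pixel_size_um = readr::col_double()))
  required <- c("field_id", "path", "genotype", "age_months", "mouse_id",
                "slice_id", "region", "pixel_size_um")
  missing_cols <- setdiff(required, names(man))
  if (length(missing_cols) > 0L) {
    stop("manifest is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(man) == 0L) return(man)
  dup <- unique(man$field_id[duplicated(man$field_id)])
  if (length(dup) > 0L) {
    stop("duplicate field_id in manifest: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(man$pixel_size_um)) || any(man$pixel_size_um <= 0)) {
    stop("manifest pixel_size_um must be positive", call. = FALSE)
  }
  if (check_paths) {
    # image paths are taken relative to the manifest's directory when not
    # found as given
    base <- dirname(path)
    resolved <- ifelse(file.exists(man$path), man$path,
                       file.path(base, basename(man$path)))
    gone <- man$field_id[!file.exists(resolved)]
    if (length(gone) > 0L) {
      stop("manifest references missing image file(s) for: ",
           paste(gone, collapse = ", "), call. = FALSE)
    }
    man$path <- resolved
  }
  man
}

#' Write / read a vessel-ROI sidecar
#'
#' The sidecar is a JSON array of `{field_id, vessel, polygon: [[x, y], ...]}`
#' records with 0-based pixel vertices, standing in for manual large-vessel
#' selections.
#'
#' @param rois Tibble as returned by [vessel_rois()].
#' @param path JSON file path.
#' @return `path` (write) or the ROI tibble (read).
#' @export
write_roi_sidecar <- function(rois, path) {
  recs <- lapply(seq_len(nrow(rois)), function(i) {
    list(field_id = rois$field_id[i], vessel = rois$vessel[i],
         polygon = unname(apply(rois$polygon[[i]], 1, c, simplify = FALSE)))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roi_sidecar
#' @export
read_roi_sidecar <- function(path) {
  recs <- jsonlite::read_json(path)
  rows <- lapply(recs, function(r) {
    poly <- do.call(rbind, lapply(r$polygon, unlist))
    colnames(poly) <- c("x", "y")
    tibble::tibble(field_id = r$field_id, vessel = as.integer(r$vessel),
                   polygon = list(poly))
  })
  dplyr::bind_rows(rows)
}
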