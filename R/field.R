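#' Multi-channel imaged field
#'
#' An `ist_field` bundles the three co-registered acquisition channels of one
#' imaged tissue field -- Hoechst (nuclei), FITC (tissue autofluorescence plus
#' lectin-stained endothelium) and Cy3 (anti-DMPO nitrone-adduct signal) --
#' together with the pixel size and the provenance labels that tie the field
#' to its cohort position.
#'
#' Pixel conventions used throughout the package: matrices are indexed
#' `[row, col]` with the origin at the top-left; coordinates reported to users
#' (centroids, vessel centers, ROI polygons) are 0-based `(x, y)` pairs where
#' `x` is the column offset and `y` the row offset. Areas are reported in
#' square micrometers via `pixel_size_um^2`, densities in counts per square
#' millimeter.
#'
#' @param hoechst,fitc,cy3 Integer matrices of identical dimensions with
#'   values in `[0, 65535]` (16-bit arbitrary units).
#' @param pixel_size_um Positive scalar, micrometers per pixel.
#' @param genotype,age_months,mouse_id,slice_id,region Provenance labels.
#' @return An object of class `ist_field`.
#' @export
ist_field <- function(hoechst, fitc, cy3, pixel_size_um,
                      genotype = NA_character_, age_months = NA_integer_,
                      mouse_id = NA_character_, slice_id = NA_character_,
                      region = NA_character_) {
  chans <- list(hoechst = hoechst, fitc = fitc, cy3 = cy3)
  for (nm in names(chans)) {
    ch <- chans[[nm]]
    if (!is.matrix(ch) || !is.numeric(ch)) {
      stop("channel '", nm, "' must be a numeric matrix", call. = FALSE)
    }
    if (!identical(dim(ch), dim(hoechst))) {
      stop("all three channels must share dimensions", call. = FALSE)
    }
    if (anyNA(ch) || min(ch) < 0 || max(ch) > 65535) {
      stop("channel '", nm, "' must lie within [0, 65535] with no NA",
           call. = FALSE)
    }
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      is.na(pixel_size_um) || pixel_size_um <= 0) {
    stop("pixel_size_um must be a positive scalar", call. = FALSE)
  }
  structure(
    list(
      hoechst = as_u16(hoechst), fitc = as_u16(fitc), cy3 = as_u16(cy3),
      pixel_size_um = as.numeric(pixel_size_um),
      provenance = list(
        genotype = as.character(genotype),
        age_months = as.integer(age_months),
        mouse_id = as.character(mouse_id),
        slice_id = as.character(slice_id),
        region = as.character(region)
      )
    ),
    class = "ist_field"
  )
}

as_u16 <- function(m) {
  d <- dim(m)
  attributes(m) <- NULL        # drop stray TIFF metadata attributes
  storage.mode(m) <- "integer"
  dim(m) <- d
  m
}

#' @export
print.ist_field <- function(x, ...) {
  d <- dim(x$fitc)
  p <- x$provenance
  cat(sprintf(
    "<ist_field> %d x %d px @ %.4g um/px (%.4g mm^2)\n",
    d[1], d[2], x$pixel_size_um, field_area_mm2(x)
  ))
  cat(sprintf("  provenance: %s, %s months, mouse %s, slice %s, %s\n",
              p$genotype, p$age_months, p$mouse_id, p$slice_id, p$region))
  invisible(x)
}

#' Field area in square millimeters
#' @param field An [ist_field()].
#' @return Scalar area in mm^2.
#' @export
field_area_mm2 <- function(field) {
  stopifnot(inherits(field, "ist_field"))
  d <- dim(field$fitc)
  prod(d) * (field$pixel_size_um / 1000)^2
}

#' @keywords internal
field_provenance_row <- function(field) {
  p <- field$provenance
  tibble::tibble(
    genotype = p$genotype, age_months = p$age_months, mouse_id = p$mouse_id,
    slice_id = p$slice_id, region = p$region
  )
}
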