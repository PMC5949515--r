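score_record <- function(field, compartment, mean_cy3, mean_fitc_reference,
                         score, auxiliary = NA_real_, flagged = FALSE,
                         field_id = NA_character_) {
  dplyr::bind_cols(
    tibble::tibble(field_id = field_id, compartment = compartment,
                   mean_cy3 = mean_cy3,
                   mean_fitc_reference = mean_fitc_reference,
                   auxiliary = auxiliary, score = score, flagged = flagged),
    field_provenance_row(field))
}

# "Tissue autofluorescence" reference: mean FITC outside all vessel masks.
# Lectin-positive endothelium is several-fold brighter than tissue in FITC,
# so leaving it in would bias the reference; the vessel mask defaults to the
# Otsu-bright class of the whole FITC channel.
#' @keywords internal
tissue_fitc_reference <- function(field, vessel_mask = NULL) {
  if (is.null(vessel_mask)) {
    vessel_mask <- matrix(FALSE, nrow(field$fitc), ncol(field$fitc))
    if (min(field$fitc) < max(field$fitc)) {
      thr <- otsu_threshold(field$fitc)
      cand <- field$fitc > thr
      # keep the carve-out only when it is a genuine lectin class, not the
      # upper noise half of a vessel-free field
      if (any(cand) && !all(cand) &&
          mean(field$fitc[cand]) >= 2.5 * mean(field$fitc[!cand])) {
        vessel_mask <- cand
      }
    }
  }
  if (all(vessel_mask)) stop("vessel mask covers the whole field",
                             call. = FALSE)
  mean(field$fitc[!vessel_mask])
}

#' Cardiomyocyte DMPO score
#'
#' Whole-field mean Cy3 (DMPO nitrone-adduct signal) divided by whole-field
#' mean FITC (tissue autofluorescence). The ratio cancels multiplicative
#' photobleaching/batch factors; the whole field stands in for the
#' cardiomyocyte compartment because vessels cover only a few percent of the
#' imaged area.
#'
#' @param field An [ist_field()].
#' @param field_id Optional id carried into the record.
#' @return One-row score tibble (`compartment = "cardiomyocyte"`).
#' @export
cardiomyocyte_score <- function(field, field_id = NA_character_) {
  stopifnot(inherits(field, "ist_field"))
  mc <- mean(field$cy3)
  mf <- mean(field$fitc)
  if (mf <= 0) stop("zero mean FITC: degenerate field", call. = FALSE)
  score_record(field, "cardiomyocyte", mc, mf, mc / mf, field_id = field_id)
}

#' Large-vessel endothelium DMPO score
#'
#' Mean Cy3 within the segmented endothelial ring, normalized to the tissue
#' autofluorescence reference (mean FITC outside vessel masks). The ring area
#' (um^2) is recorded as the auxiliary value; with `extra_area_norm = TRUE`
#' the score is additionally divided by the ring area (off by default, since
#' a mean over the mask already accounts for area).
#'
#' @param field An [ist_field()].
#' @param ring_mask Logical mask from [segment_endothelial_ring()].
#' @param vessel_mask Optional mask of all vessel pixels to exclude from the
#'   FITC reference (defaults to the whole-field Otsu-bright class).
#' @param extra_area_norm Divide again by ring area.
#' @param min_ring_area_um2 Rings below this area flag the record.
#' @param field_id Optional id.
#' @return One-row score tibble (`compartment = "large_vessel_endothelium"`).
#' @export
vessel_endothelium_score <- function(field, ring_mask, vessel_mask = NULL,
                                     extra_area_norm = FALSE,
                                     min_ring_area_um2 = 50,
                                     field_id = NA_character_) {
  stopifnot(inherits(field, "ist_field"))
  if (!any(ring_mask)) stop("empty ring mask", call. = FALSE)
  area <- sum(ring_mask) * field$pixel_size_um^2
  mc <- mean(field$cy3[ring_mask])
  ref <- tissue_fitc_reference(field, vessel_mask)
  score <- mc / ref
  if (extra_area_norm) score <- score / area
  score_record(field, "large_vessel_endothelium", mc, ref, score,
               auxiliary = area, flagged = area < min_ring_area_um2,
               field_id = field_id)
}

#' Microvessel DMPO score
#'
#' Mean Cy3 within the lectin-positive microvessel pixels, normalized to the
#' tissue autofluorescence reference and to the microvessel density; the
#' density (counts/mm^2) is the auxiliary value, making the score's literal
#' units mm^2. A field with no detected microvessels yields a flagged record
#' with an undefined (NA) score, to be excluded from group summaries rather
#' than zero-filled.
#'
#' @param field An [ist_field()].
#' @param detection Result of [detect_microvessels()] (or an `ist_objects`
#'   plus explicit `density`).
#' @param density Optional density override, counts/mm^2.
#' @param field_id Optional id.
#' @return One-row score tibble (`compartment = "microvessel_endothelium"`).
#' @export
microvessel_score <- function(field, detection, density = NULL,
                              field_id = NA_character_) {
  stopifnot(inherits(field, "ist_field"))
  objects <- if (inherits(detection, "ist_objects")) detection
             else detection$objects
  if (is.null(density)) {
    density <- if (inherits(detection, "ist_objects")) {
      nrow(objects$objects) / field_area_mm2(field)
    } else detection$density
  }
  mask <- objects$labels > 0L
  if (density <= 0 || !any(mask)) {
    return(score_record(field, "microvessel_endothelium", NA_real_, NA_real_,
                        NA_real_, auxiliary = density, flagged = TRUE,
                        field_id = field_id))
  }
  mc <- mean(field$cy3[mask])
  ref <- tissue_fitc_reference(field)
  score_record(field, "microvessel_endothelium", mc, ref,
               (mc / ref) / density, auxiliary = density,
               field_id = field_id)
}

#' Microvessel density
#'
#' @param labeled An `ist_objects` (or an object count).
#' @param field_area_mm2 Field area in mm^2, > 0.
#' @return Density in counts/mm^2.
#' @export
microvessel_density <- function(labeled, field_area_mm2) {
  if (field_area_mm2 <= 0) stop("field area must be > 0", call. = FALSE)
  n <- if (inherits(labeled, "ist_objects")) nrow(labeled$objects)
       else as.numeric(labeled)
  n / field_area_mm2
}

#' Lectin-positive vessel area fraction of a field
#'
#' Fraction of field pixels that are lectin-positive (any vessel size),
#' measured as the Otsu-bright class of the FITC channel. The same
#' foreground/background contrast guard as in [detect_microvessels()] returns
#' 0 for fields without lectin-positive structures.
#'
#' @param field An [ist_field()].
#' @param min_contrast Minimum foreground/background mean ratio.
#' @return Fraction in `[0, 1)`.
#' @export
vessel_area_fraction <- function(field, min_contrast = 2.5) {
  stopifnot(inherits(field, "ist_field"))
  if (min(field$fitc) == max(field$fitc)) return(0)  # featureless field
  thr <- otsu_threshold(field$fitc)
  mask <- field$fitc > thr
  if (!any(mask) || all(mask) ||
      mean(field$fitc[mask]) < min_contrast * mean(field$fitc[!mask])) {
    return(0)
  }
  mean(mask)
}

#' Normalize case scores to age-matched controls
#'
#' Divides each case score by the median of the age-matched control scores,
#' making group comparisons independent of per-age processing (fixation
#' batch) effects; a control group normalized to itself has median exactly 1.
#'
#' @param case_scores Numeric vector.
#' @param control_scores Numeric vector of the matched control group.
#' @return Normalized numeric vector.
#' @export
normalize_to_control <- function(case_scores, control_scores) {
  control_scores <- control_scores[!is.na(control_scores)]
  if (length(control_scores) == 0L) {
    stop("empty control group", call. = FALSE)
  }
  m <- median(control_scores)
  if (m <= 0) stop("control median must be > 0", call. = FALSE)
  case_scores / m
}

#' Control-normalize a long score table
#'
#' Within each age-by-compartment (by default) stratum, divides every score
#' by the median of that stratum's control-genotype scores.
#'
#' @param scores Tibble with at least `genotype`, `score` and the grouping
#'   columns.
#' @param value Column to normalize (default `score`).
#' @param by Stratification columns.
#' @param control Genotype label of the control group.
#' @return Input tibble with a `normalized` column added.
#' @export
normalize_scores <- function(scores, value = "score",
                             by = c("age_months", "compartment"),
                             control = "control") {
  by <- intersect(by, names(scores))
  scores |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::mutate(normalized = normalize_to_control(
      .data[[value]], .data[[value]][.data$genotype == control])) |>
    dplyr::ungroup()
}

#' Median and interquartile range of a score sample
#'
#' Group results are expressed as median and Q1-Q3 interquartile range;
#' quantiles use linear interpolation (type 7). `NA` scores (flagged
#' undefined records) are dropped.
#'
#' @param scores Numeric vector (n >= 1 after NA removal).
#' @return One-row tibble `n`, `median`, `q1`, `q3`.
#' @export
summarize_group <- function(scores) {
  scores <- scores[!is.na(scores)]
  if (length(scores) < 1L) stop("no defined scores to summarize",
                                call. = FALSE)
  q <- quantile(scores, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble::tibble(n = length(scores), median = q[2], q1 = q[1], q3 = q[3])
}

#' Group-wise median/IQR summaries of a score table
#'
#' @param scores Tibble with a value column and grouping columns.
#' @param value Column to summarize.
#' @param by Grouping columns (defaults to genotype, age, compartment where
#'   present).
#' @return Tibble of group keys with `n`, `median`, `q1`, `q3`.
#' @export
summarize_scores <- function(scores, value = "score",
                             by = c("genotype", "age_months", "compartment")) {
  by <- intersect(by, names(scores))
  scores |>
    dplyr::filter(!is.na(.data[[value]])) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::reframe(summarize_group(.data[[value]]))
}
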