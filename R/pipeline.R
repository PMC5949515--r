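#' Load a study configuration from YAML
#'
#' The YAML mirrors [group_spec()]: a top-level `groups:` list whose entries
#' carry `group_spec` arguments (`dmpo_level` and `fields_per_region` as
#' named mappings). Unknown keys are reported by name.
#'
#' @param path YAML file.
#' @return List of `ist_group_spec`.
#' @export
load_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$groups) || length(cfg$groups) == 0L) {
    stop("study config must contain a non-empty 'groups' list", call. = FALSE)
  }
  known <- names(formals(group_spec))
  lapply(cfg$groups, function(g) {
    bad <- setdiff(names(g), known)
    if (length(bad) > 0L) {
      stop("unknown study-config key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    for (nm in c("dmpo_level", "fields_per_region")) {
      if (!is.null(g[[nm]])) g[[nm]] <- unlist(g[[nm]])
    }
    do.call(group_spec, g)
  })
}

#' Generate a synthetic cohort to disk (driver)
#'
#' @param config Path to a YAML study config, a list of [group_spec()]s, or
#'   `NULL` for [default_study_config()].
#' @param seed Root seed.
#' @param out_dir Output directory (images, manifest, truth, ROI sidecar,
#'   run record).
#' @param force Overwrite existing images.
#' @return The cohort list from [generate_cohort()], invisibly.
#' @export
ist_synth <- function(config = NULL, seed = 1L, out_dir, force = FALSE) {
  if (is.null(config)) {
    config <- default_study_config()
  } else if (is.character(config)) {
    config <- load_study_config(config)
  }
  invisible(generate_cohort(config, seed = seed, out_dir = out_dir,
                            force = force, keep_fields = FALSE))
}

score_field_all <- function(field, field_id, config, field_rois = NULL) {
  cardio <- cardiomyocyte_score(field, field_id = field_id)
  det <- detect_microvessels(field, config)
  micro <- microvessel_score(field, det, field_id = field_id)
  metrics <- dplyr::bind_cols(
    tibble::tibble(
      field_id = field_id,
      cardiomyocyte_score = cardio$score,
      microvessel_density = det$density,
      microvessel_score = micro$score,
      microvessel_flagged = micro$flagged,
      vessel_area_fraction = vessel_area_fraction(field)),
    field_provenance_row(field))
  vessels <- NULL
  if (!is.null(field_rois) && nrow(field_rois) > 0L) {
    vessels <- purrr::map_dfr(seq_len(nrow(field_rois)), function(i) {
      ring <- segment_endothelial_ring(field, field_rois$polygon[[i]],
                                       min_ring_area_um2 =
                                         config$min_ring_area_um2)
      rec <- vessel_endothelium_score(
        field, ring, extra_area_norm = config$extra_area_norm,
        min_ring_area_um2 = config$min_ring_area_um2, field_id = field_id)
      rec$vessel <- field_rois$vessel[i]
      rec$radius_um <- estimate_vessel_radius(ring, field$pixel_size_um)
      rec
    })
  }
  list(metrics = metrics, vessels = vessels)
}

#' Analyze a cohort end to end (driver)
#'
#' For every field: cardiomyocyte score, microvessel detection (density and
#' score) and vessel area fraction; for fields with ROI entries, large-vessel
#' endothelial ring scores and radii. Scores are then control-normalized per
#' age and compartment, summarized as median (Q1-Q3), and compared: an
#' age-matched two-group test per compartment and age (distribution-adaptive
#' decision tree), a Kruskal-Wallis + Dunn progression analysis within the
#' case genotype, and a linear trend contrast on microvessel density.
#'
#' @param manifest Manifest tibble or CSV path.
#' @param rois ROI tibble ([vessel_rois()]), sidecar JSON path, or `NULL`
#'   (large-vessel analysis skipped with a warning).
#' @param fields Optional named list of in-memory [ist_field()]s keyed by
#'   `field_id` (otherwise images are read from `manifest$path`).
#' @param config An [pipeline_config()].
#' @param out_dir Optional directory for CSV reports and summary figures.
#' @param case_genotype Genotype compared against `"control"`.
#' @return An `ist_analysis` list: `field_metrics`, `vessel_scores`,
#'   `scores` (long), `normalized`, `summaries`, `group_tests`, `omnibus`,
#'   `trend`, `config`.
#' @export
ist_analyze <- function(manifest, rois = NULL, fields = NULL,
                        config = pipeline_config(), out_dir = NULL,
                        case_genotype = "Tg") {
  if (is.character(manifest)) manifest <- load_manifest(manifest)
  if (is.character(rois)) rois <- read_roi_sidecar(rois)
  if (is.null(rois)) {
    warning("no vessel ROIs supplied: large-vessel analysis skipped",
            call. = FALSE)
  }
  res <- purrr::map(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    field <- if (!is.null(fields)) {
      fields[[row$field_id]]
    } else {
      read_field(row$path, pixel_size_override = row$pixel_size_um,
                 channel_order = config$channel_order,
                 genotype = row$genotype, age_months = row$age_months,
                 mouse_id = row$mouse_id, slice_id = row$slice_id,
                 region = row$region)
    }
    if (is.null(field)) stop("no image for field ", row$field_id,
                             call. = FALSE)
    fr <- if (!is.null(rois)) rois[rois$field_id == row$field_id, ] else NULL
    score_field_all(field, row$field_id, config, fr)
  })
  field_metrics <- purrr::map_dfr(res, "metrics")
  vessel_scores <- purrr::map_dfr(res, "vessels")

  scores <- dplyr::bind_rows(
    field_metrics |>
      dplyr::transmute(.data$field_id, compartment = "cardiomyocyte",
                       score = .data$cardiomyocyte_score, .data$genotype,
                       .data$age_months, .data$mouse_id, .data$region),
    field_metrics |>
      dplyr::filter(!.data$microvessel_flagged) |>
      dplyr::transmute(.data$field_id,
                       compartment = "microvessel_endothelium",
                       score = .data$microvessel_score, .data$genotype,
                       .data$age_months, .data$mouse_id, .data$region),
    if (nrow(vessel_scores) > 0L) {
      vessel_scores |>
        dplyr::filter(!.data$flagged) |>
        dplyr::select("field_id", "compartment", "score", "genotype",
                      "age_months", "mouse_id", "region")
    })

  normalized <- normalize_scores(scores)
  summaries <- summarize_scores(normalized, value = "normalized")

  group_tests <- scores |>
    dplyr::group_by(.data$compartment, .data$age_months) |>
    dplyr::group_modify(function(d, key) {
      x <- d$score[d$genotype == case_genotype]
      y <- d$score[d$genotype == "control"]
      if (length(x) < 2L || length(y) < 2L) return(tibble::tibble())
      two_group_test(x, y, alpha = config$alpha)
    }) |>
    dplyr::ungroup()
  if (nrow(group_tests) > 0L) {
    group_tests$stars <- significance_stars(group_tests$p_value)
  }

  omnibus <- list()
  for (cmp in unique(normalized$compartment)) {
    d <- normalized[normalized$compartment == cmp &
                      normalized$genotype == case_genotype, ]
    ages <- sort(unique(d$age_months))
    if (length(ages) >= 3L && all(table(d$age_months) >= 2L)) {
      omnibus[[cmp]] <- kruskal_dunn(
        data.frame(value = d$normalized,
                   group = paste0(d$age_months, "m")),
        alpha = config$alpha, adjust = config$posthoc_adjust)
    }
  }

  trend <- NULL
  dens <- field_metrics[field_metrics$genotype == case_genotype, ]
  if (length(unique(dens$age_months)) >= 3L) {
    dens <- dens[order(dens$age_months), ]
    trend <- linear_trend(
      data.frame(value = dens$microvessel_density,
                 group = paste0(dens$age_months, "m")),
      alpha = config$alpha)
  }

  out <- structure(list(
    field_metrics = field_metrics, vessel_scores = vessel_scores,
    scores = scores, normalized = normalized, summaries = summaries,
    group_tests = group_tests, omnibus = omnibus, trend = trend,
    config = config), class = "ist_analysis")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(field_metrics, file.path(out_dir, "field_metrics.csv"))
    if (nrow(vessel_scores) > 0L) {
      readr::write_csv(vessel_scores, file.path(out_dir, "vessel_scores.csv"))
    }
    readr::write_csv(normalized, file.path(out_dir, "scores_normalized.csv"))
    readr::write_csv(summaries, file.path(out_dir, "group_summaries.csv"))
    readr::write_csv(group_tests, file.path(out_dir, "stats_report.csv"))
    for (cmp in unique(normalized$compartment)) {
      p <- plot_group_scores(normalized[normalized$compartment == cmp, ],
                             title = cmp)
      ggplot2::ggsave(file.path(out_dir, paste0("summary_", cmp, ".png")),
                      p, width = 6, height = 4, dpi = 150)
    }
  }
  out
}

#' @export
print.ist_analysis <- function(x, ...) {
  cat(sprintf("<ist_analysis> %d fields, %d vessel scores, %d compartments\n",
              nrow(x$field_metrics), nrow(x$vessel_scores),
              length(unique(x$scores$compartment))))
  cat("\nGroup summaries (control-normalized, median [Q1-Q3]):\n")
  print(x$summaries, n = 30)
  invisible(x)
}
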