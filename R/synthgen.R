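#' Group specification for the synthetic cohort generator
#'
#' A `group_spec` captures everything the generator needs for one
#' genotype-by-age group: the sampling design (mice, slices, fields per heart
#' region), the vessel geometry (log-normal large-vessel radii, capillary
#' density, lectin-positive area fraction), the compartment-specific DMPO
#' (Cy3) intensity levels, the autofluorescence (FITC) level, and the nuisance
#' magnitudes (photobleaching per slice, fixation batch per age, per-mouse
#' random effect) that the downstream ratio normalizations exist to cancel.
#'
#' Intensities are arbitrary 16-bit units: the imaging protocol being emulated
#' reports no absolute fluorescence calibration, so only ratios are
#' meaningful. Log-normal spreads are parameterized as `sdlog`; the defaults
#' for the area-fraction and radius distributions are fitted from reported
#' quartiles as `mean(|ln(Q3/median)|, |ln(median/Q1)|) / 0.6745`.
#'
#' @param genotype `"Tg"` or `"control"`.
#' @param age_months Integer age of the group in months.
#' @param n_mice,slices_per_mouse Sampling design counts.
#' @param fields_per_region Named integer vector; names must be a subset of
#'   `left_ventricle`, `right_ventricle`, `septum`, `papillary`.
#' @param microvessel_density_true True capillary density, counts/mm^2.
#' @param large_vessel_radius_dist List `(median_um, sdlog)` for the outer
#'   radius of large-vessel endothelial rings.
#' @param large_vessels_per_field Number of large vessels placed per field
#'   (default 0; dedicated vessel fields use 1).
#' @param area_fraction_dist List `(median, sdlog)` of the per-field target
#'   lectin-positive area fraction (a fraction, not percent).
#' @param dmpo_level Named vector of mean Cy3 intensity (a.u.) for
#'   `cardiomyocyte`, `large_vessel_endothelium`, `microvessel_endothelium`.
#' @param autofluorescence_level Mean FITC intensity of tissue (a.u.).
#' @param lectin_level FITC intensity of lectin-positive endothelium (a.u.).
#' @param lumen_level FITC intensity inside large-vessel lumina (a.u.).
#' @param noise_sd Additive Gaussian noise s.d. per channel (a.u.).
#' @param mouse_sdlog,bleach_sdlog,batch_sdlog Log-normal s.d. of the
#'   per-mouse DMPO random effect, per-slice bleach factor, and per-age batch
#'   factor.
#' @param nuclei_per_mm2,nucleus_level Hoechst channel nuclei density and
#'   intensity.
#' @param field_px,pixel_size_um Field edge length in pixels and pixel size
#'   in micrometers (defaults 1024 px at 0.25 um/px, i.e. 0.0655 mm^2).
#' @return A list of class `ist_group_spec`.
#' @export
group_spec <- function(genotype = c("control", "Tg"),
                       age_months = 8L,
                       n_mice = 5L,
                       slices_per_mouse = 2L,
                       fields_per_region = c(left_ventricle = 3L,
                                             right_ventricle = 3L,
                                             septum = 3L,
                                             papillary = 1L),
                       microvessel_density_true = 2000,
                       large_vessel_radius_dist = list(median_um = 42.9,
                                                       sdlog = 0.5583),
                       large_vessels_per_field = 0L,
                       area_fraction_dist = list(median = 0.028,
                                                 sdlog = 0.6554),
                       dmpo_level = c(cardiomyocyte = 1000,
                                      large_vessel_endothelium = 1200,
                                      microvessel_endothelium = 1200),
                       autofluorescence_level = 1500,
                       lectin_level = 8000,
                       lumen_level = 400,
                       noise_sd = 150,
                       mouse_sdlog = 0.15,
                       bleach_sdlog = 0.15,
                       batch_sdlog = 0.2,
                       nuclei_per_mm2 = 1500,
                       nucleus_level = 20000,
                       field_px = 1024L,
                       pixel_size_um = 0.25) {
  genotype <- match.arg(genotype)
  compartments <- c("cardiomyocyte", "large_vessel_endothelium",
                    "microvessel_endothelium")
  regions <- c("left_ventricle", "right_ventricle", "septum", "papillary")
  if (!all(names(fields_per_region) %in% regions)) {
    stop("fields_per_region names must be a subset of: ",
         paste(regions, collapse = ", "), call. = FALSE)
  }
  if (!all(compartments %in% names(dmpo_level))) {
    stop("dmpo_level must name all three compartments", call. = FALSE)
  }
  if (any(c(dmpo_level, autofluorescence_level, lectin_level, lumen_level,
            noise_sd) < 0)) {
    stop("intensity parameters must be >= 0", call. = FALSE)
  }
  if (microvessel_density_true < 0) {
    stop("microvessel_density_true must be >= 0", call. = FALSE)
  }
  if (large_vessel_radius_dist$sdlog <= 0 || area_fraction_dist$sdlog <= 0) {
    stop("spread parameters must be > 0", call. = FALSE)
  }
  spec <- list(
    genotype = genotype, age_months = as.integer(age_months),
    n_mice = as.integer(n_mice),
    slices_per_mouse = as.integer(slices_per_mouse),
    fields_per_region = fields_per_region,
    microvessel_density_true = microvessel_density_true,
    large_vessel_radius_dist = large_vessel_radius_dist,
    large_vessels_per_field = as.integer(large_vessels_per_field),
    area_fraction_dist = area_fraction_dist,
    dmpo_level = dmpo_level[compartments],
    autofluorescence_level = autofluorescence_level,
    lectin_level = lectin_level, lumen_level = lumen_level,
    noise_sd = noise_sd, mouse_sdlog = mouse_sdlog,
    bleach_sdlog = bleach_sdlog, batch_sdlog = batch_sdlog,
    nuclei_per_mm2 = nuclei_per_mm2, nucleus_level = nucleus_level,
    field_px = as.integer(field_px), pixel_size_um = pixel_size_um
  )
  class(spec) <- "ist_group_spec"
  spec
}

# Default Tg/control effect sizes per age. The emulated readouts are normalized
# (no absolute intensities are published), so these ratios are configuration
# values chosen to rise with age in all compartments, steepest by 16 months;
# microvessel density declines only in the Tg groups, reaching half the
# control value at 16 months.
ist_default_effects <- function() {
  tibble::tibble(
    age_months = c(8L, 10L, 12L, 14L, 16L),
    cardiomyocyte_ratio = c(1.0, 1.3, 1.6, 2.0, 3.0),
    large_vessel_ratio = c(1.0, 1.4, 1.8, 2.4, 3.0),
    microvessel_ratio = c(1.0, 1.3, 1.7, 2.2, 3.5),
    density_control = c(2000, 2000, 2000, 2000, 2000),
    density_tg = c(2000, 1700, 1400, 1200, 1000),
    n_mice = c(5L, 5L, 5L, 6L, 4L)
  )
}

#' Default group specification for one genotype-by-age group
#'
#' Applies the package's default effect-size table: control groups keep a
#' capillary density of 2,000/mm^2 at all ages while Tg groups decline to
#' 1,000/mm^2 by 16 months; Tg DMPO levels exceed controls by an
#' age-increasing ratio in all three compartments. Area-fraction medians are
#' 2.8% (control) and 3.1% (Tg), with log-normal spreads fitted from the
#' reported quartiles (1.9-4.6% and 1.9-5.1%).
#'
#' @param genotype `"control"` or `"Tg"`.
#' @param age_months One of 8, 10, 12, 14, 16.
#' @param ... Overrides passed on to [group_spec()].
#' @return An `ist_group_spec`.
#' @export
default_group_spec <- function(genotype = c("control", "Tg"),
                               age_months = 8L, ...) {
  genotype <- match.arg(genotype)
  eff <- ist_default_effects()
  row <- eff[eff$age_months == as.integer(age_months), ]
  if (nrow(row) != 1L) {
    stop("age_months must be one of ", paste(eff$age_months, collapse = ", "),
         call. = FALSE)
  }
  base_dmpo <- c(cardiomyocyte = 1000, large_vessel_endothelium = 1200,
                 microvessel_endothelium = 1200)
  if (genotype == "Tg") {
    dmpo <- base_dmpo * c(row$cardiomyocyte_ratio, row$large_vessel_ratio,
                          row$microvessel_ratio)
    dens <- row$density_tg
    afd <- list(median = 0.031, sdlog = 0.7320)
  } else {
    dmpo <- base_dmpo
    dens <- row$density_control
    afd <- list(median = 0.028, sdlog = 0.6554)
  }
  args <- list(genotype = genotype, age_months = age_months,
               n_mice = row$n_mice, microvessel_density_true = dens,
               dmpo_level = dmpo, area_fraction_dist = afd)
  override <- list(...)
  args[names(override)] <- override
  do.call(group_spec, args)
}

#' Default study configuration: two genotypes across five ages
#'
#' @param ages Integer ages in months (default 8, 10, 12, 14, 16).
#' @param ... Overrides applied to every group via [default_group_spec()].
#' @return A list of `ist_group_spec`, one per genotype-by-age group.
#' @export
default_study_config <- function(ages = c(8L, 10L, 12L, 14L, 16L), ...) {
  specs <- list()
  for (a in ages) {
    for (g in c("control", "Tg")) {
      specs[[paste0(g, "_", a, "m")]] <- default_group_spec(g, a, ...)
    }
  }
  specs
}

#' Dedicated large-vessel field specification
#'
#' Fields intended for large-coronary-vessel analysis: one vessel per field on
#' a 1280 x 1280 px (320 um) field so that radii drawn from the default
#' log-normal (median 42.9 um) almost never hit the field border.
#'
#' @param genotype `"control"` or `"Tg"`.
#' @param age_months Group age.
#' @param ... Overrides passed to [default_group_spec()].
#' @return An `ist_group_spec` with `large_vessels_per_field = 1`.
#' @export
vessel_field_spec <- function(genotype = "control", age_months = 8L, ...) {
  default_group_spec(genotype, age_months,
                     large_vessels_per_field = 1L, field_px = 1280L,
                     fields_per_region = c(left_ventricle = 3L), ...)
}

# Linear indices of the pixels whose centers fall in a disc/annulus.
# cx, cy are 0-based (x = col, y = row) continuous pixel coordinates; radii
# in pixels. Returning indices (rather than painting matrices in place)
# avoids one full-matrix copy per object.
annulus_indices <- function(nr, nc, cx, cy, r_out, r_in = -1) {
  rows <- max(1L, floor(cy + 1 - r_out)):min(nr, ceiling(cy + 1 + r_out))
  cols <- max(1L, floor(cx + 1 - r_out)):min(nc, ceiling(cx + 1 + r_out))
  dy2 <- ((rows - 1) - cy)^2
  dx2 <- ((cols - 1) - cx)^2
  d2 <- outer(dy2, dx2, `+`)
  sel <- which(d2 <= r_out^2 & d2 > r_in^2)
  rr <- rows[(sel - 1L) %% length(rows) + 1L]
  cc <- cols[(sel - 1L) %/% length(rows) + 1L]
  rr + (cc - 1L) * nr
}

#' Generate one synthetic triple-channel field with ground truth
#'
#' Builds a field as the imaging protocol sees it: the FITC channel is smooth
#' cardiomyocyte autofluorescence texture with bright lectin-positive
#' endothelium (capillary discs, large-vessel annuli); the Cy3 channel is the
#' compartment-wise DMPO nitrone-adduct level; Hoechst is scattered nuclei.
#' Gaussian noise is added per channel, and FITC and Cy3 are jointly scaled by
#' `bleach * batch` (photobleaching and fixation-batch nuisance), then clipped
#' to the 16-bit range. Identical `(spec, region, seed)` give bit-identical
#' output.
#'
#' Capillary radii are first drawn uniformly on 1.5-4 um and then rescaled
#' (clamped to 1.4-4.5 um) so that total painted vessel area matches the
#' field's target area fraction drawn from `spec$area_fraction_dist`; discs
#' are placed without contact (>= 3 px edge gap) so the morphological chain
#' does not merge neighbours.
#'
#' @param spec An [group_spec()].
#' @param region Heart region label for provenance.
#' @param seed Integer seed for this field's RNG stream.
#' @param bleach,batch Positive nuisance factors; drawn log-normally from the
#'   spec's `bleach_sdlog`/`batch_sdlog` when `NULL`.
#' @param mouse_effect Multiplier applied to all DMPO levels (per-mouse
#'   random effect; 1 for a standalone field).
#' @param mouse_id,slice_id Provenance labels.
#' @return A list with elements `field` (an [ist_field()]) and `truth`
#'   (one-row tibble: microvessel count/centers/radii, large-vessel
#'   geometry, achieved lectin-positive area fraction, realized DMPO levels,
#'   bleach and batch factors).
#' @export
generate_field <- function(spec, region = "left_ventricle", seed = 1L,
                           bleach = NULL, batch = NULL, mouse_effect = 1,
                           mouse_id = "m1", slice_id = "s1") {
  stopifnot(inherits(spec, "ist_group_spec"))
  n <- spec$field_px
  ps <- spec$pixel_size_um
  area_mm2 <- (n * ps / 1000)^2
  area_um2 <- area_mm2 * 1e6
  withr::with_seed(as.integer(seed), {
    if (is.null(bleach)) bleach <- rlnorm(1, 0, spec$bleach_sdlog)
    if (is.null(batch)) batch <- rlnorm(1, 0, spec$batch_sdlog)
    if (bleach <= 0 || batch <= 0) {
      stop("bleach and batch factors must be > 0", call. = FALSE)
    }
    micro_idx <- list()  # linear pixel indices per compartment
    ring_idx <- list()
    lumen_idx <- list()

    ## large vessels ---------------------------------------------------------
    lv <- tibble::tibble(cx = numeric(), cy = numeric(),
                         inner_radius_um = numeric(),
                         outer_radius_um = numeric())
    max_r_um <- min(0.45 * n * ps, 150)
    if (spec$large_vessels_per_field > 0L) {
      for (k in seq_len(spec$large_vessels_per_field)) {
        r_out <- Inf
        for (try in 1:50) {
          r_out <- rlnorm(1, log(spec$large_vessel_radius_dist$median_um),
                          spec$large_vessel_radius_dist$sdlog)
          if (r_out <= max_r_um) break
        }
        r_out <- min(r_out, max_r_um)
        thick <- runif(1, 2, 5)
        r_in <- max(r_out - thick, 0.5)
        r_out_px <- r_out / ps
        margin <- r_out_px + 12  # leaves room for the padded ROI polygon
        placed <- FALSE
        for (try in 1:200) {
          cx <- runif(1, margin, n - 1 - margin)
          cy <- runif(1, margin, n - 1 - margin)
          ok <- nrow(lv) == 0L ||
            all(sqrt((lv$cx - cx)^2 + (lv$cy - cy)^2) >
                  (lv$outer_radius_um + r_out) / ps + 10)
          if (ok) { placed <- TRUE; break }
        }
        if (!placed) {
          stop(sprintf(
            "could not place large vessel %d (radius %.1f um) in a %d px field after 200 tries",
            k, r_out, n), call. = FALSE)
        }
        lumen_idx[[k]] <- annulus_indices(n, n, cx, cy, r_in / ps)
        ring_idx[[k]] <- annulus_indices(n, n, cx, cy, r_out_px, r_in / ps)
        lv <- dplyr::bind_rows(lv, tibble::tibble(
          cx = cx, cy = cy, inner_radius_um = r_in, outer_radius_um = r_out))
      }
    }
    ring_area_um2 <- sum(pi * (lv$outer_radius_um^2 - lv$inner_radius_um^2))

    ## capillaries -----------------------------------------------------------
    n_micro <- if (spec$microvessel_density_true > 0) {
      rpois(1, spec$microvessel_density_true * area_mm2)
    } else 0L
    target_frac <- min(rlnorm(1, log(spec$area_fraction_dist$median),
                              spec$area_fraction_dist$sdlog), 0.25)
    centers <- matrix(numeric(0), 0, 2)
    radii_um <- numeric(0)
    if (n_micro > 0L) {
      cap_target <- target_frac * area_um2 - ring_area_um2
      radii_um <- runif(n_micro, 1.5, 2.5)
      if (cap_target > 0) {
        s <- sqrt(cap_target / sum(pi * radii_um^2))
        radii_um <- pmin(pmax(radii_um * s, 1.4), 4.5)
      } else {
        radii_um <- rep(1.4, n_micro)
      }
      r_px <- radii_um / ps
      gap <- 3
      cxs <- numeric(n_micro); cys <- numeric(n_micro)
      for (i in seq_len(n_micro)) {
        m_i <- r_px[i] + 2
        placed <- FALSE
        for (try in 1:200) {
          cx <- runif(1, m_i, n - 1 - m_i)
          cy <- runif(1, m_i, n - 1 - m_i)
          ok <- TRUE
          if (i > 1L) {
            j <- seq_len(i - 1L)
            ok <- all((cxs[j] - cx)^2 + (cys[j] - cy)^2 >
                        (r_px[j] + r_px[i] + gap)^2)
          }
          if (ok && nrow(lv) > 0L) {
            ok <- all((lv$cx - cx)^2 + (lv$cy - cy)^2 >
                        (lv$outer_radius_um / ps + r_px[i] + gap)^2)
          }
          if (ok) { placed <- TRUE; break }
        }
        if (!placed) {
          stop(sprintf(
            "microvessel placement failed at disc %d of %d (density %.0f/mm^2, field %.4f mm^2): field too crowded",
            i, n_micro, spec$microvessel_density_true, area_mm2),
            call. = FALSE)
        }
        cxs[i] <- cx; cys[i] <- cy
        micro_idx[[i]] <- annulus_indices(n, n, cx, cy, r_px[i])
      }
      centers <- cbind(x = cxs, y = cys)
    }
    micro_idx <- unlist(micro_idx, use.names = FALSE)
    ring_idx <- unlist(ring_idx, use.names = FALSE)
    lumen_idx <- unlist(lumen_idx, use.names = FALSE)

    ## channels --------------------------------------------------------------
    coarse <- matrix(rnorm(33 * 33), 33, 33)
    tex <- pmax(1 + 0.12 * bilinear_upscale(coarse, n, n), 0.5)
    dmpo <- spec$dmpo_level * mouse_effect

    fitc <- spec$autofluorescence_level * tex
    fitc[micro_idx] <- spec$lectin_level
    fitc[ring_idx] <- spec$lectin_level
    fitc[lumen_idx] <- spec$lumen_level
    fitc <- fitc + rnorm(n * n, 0, spec$noise_sd)

    cy3 <- matrix(dmpo[["cardiomyocyte"]], n, n)
    cy3[micro_idx] <- dmpo[["microvessel_endothelium"]]
    cy3[ring_idx] <- dmpo[["large_vessel_endothelium"]]
    cy3[lumen_idx] <- 200
    cy3 <- cy3 + rnorm(n * n, 0, spec$noise_sd)

    f <- bleach * batch
    fitc <- pmin(pmax(round(fitc * f), 0), 65535)
    cy3 <- pmin(pmax(round(cy3 * f), 0), 65535)

    hoechst <- matrix(300 + rnorm(n * n, 0, spec$noise_sd / 2), n, n)
    n_nuc <- rpois(1, spec$nuclei_per_mm2 * area_mm2)
    if (n_nuc > 0L) {
      nx <- runif(n_nuc, 0, n - 1); ny <- runif(n_nuc, 0, n - 1)
      nr <- runif(n_nuc, 2.5, 3.5) / ps
      nuc_idx <- unlist(lapply(seq_len(n_nuc), function(i) {
        annulus_indices(n, n, nx[i], ny[i], nr[i])
      }), use.names = FALSE)
      hoechst[nuc_idx] <- spec$nucleus_level
    }
    hoechst <- pmin(pmax(round(hoechst), 0), 65535)

    field <- ist_field(hoechst, fitc, cy3, ps,
                       genotype = spec$genotype,
                       age_months = spec$age_months,
                       mouse_id = mouse_id, slice_id = slice_id,
                       region = region)
    truth <- tibble::tibble(
      field_id = NA_character_,
      microvessel_count = nrow(centers),
      achieved_vessel_area_fraction =
        (length(micro_idx) + length(ring_idx)) / (as.numeric(n) * n),
      target_area_fraction = target_frac,
      bleach_factor = bleach, batch_factor = batch,
      mouse_effect = mouse_effect,
      dmpo_cardiomyocyte = dmpo[["cardiomyocyte"]],
      dmpo_large_vessel = dmpo[["large_vessel_endothelium"]],
      dmpo_microvessel = dmpo[["microvessel_endothelium"]],
      microvessel_centers = list(centers),
      microvessel_radii_um = list(radii_um),
      large_vessels = list(lv)
    )
    list(field = field, truth = truth)
  })
}

#' Apply photobleaching/batch nuisance factors to a field
#'
#' Multiplies the FITC and Cy3 channels by `bleach * batch` (rounded, clipped
#' to 16 bits); Hoechst is unchanged. Ratio-normalized scores are invariant
#' to this operation (up to integer rounding) -- that invariance is the whole
#' point of the autofluorescence normalization.
#'
#' @param field An [ist_field()].
#' @param bleach,batch Positive scalars.
#' @return A new `ist_field`.
#' @export
apply_nuisance <- function(field, bleach, batch) {
  stopifnot(inherits(field, "ist_field"))
  if (!is.numeric(bleach) || !is.numeric(batch) || bleach <= 0 || batch <= 0) {
    stop("bleach and batch must be positive scalars", call. = FALSE)
  }
  f <- bleach * batch
  p <- field$provenance
  ist_field(field$hoechst,
            pmin(pmax(round(field$fitc * f), 0), 65535),
            pmin(pmax(round(field$cy3 * f), 0), 65535),
            field$pixel_size_um,
            genotype = p$genotype, age_months = p$age_months,
            mouse_id = p$mouse_id, slice_id = p$slice_id, region = p$region)
}

#' Generate a full synthetic cohort
#'
#' Iterates over groups, mice, slices, regions and fields, drawing one
#' per-mouse random effect per mouse, one bleach factor per slice, and one
#' batch factor per age *shared by both genotypes of that age* (the groups of
#' one age are processed together, so fixation-batch effects are common to
#' them). Per-field RNG streams are derived by stable hashing of
#' `(root seed, group, mouse, slice, region, index)`, so a cohort is
#' reproducible and insensitive to generation order.
#'
#' @param config List of [group_spec()] objects (see
#'   [default_study_config()]).
#' @param seed Root integer seed.
#' @param out_dir If non-`NULL`, fields are written as multi-page 16-bit
#'   TIFFs plus `manifest.csv`, `truth.csv`, `rois.json` (when large vessels
#'   are present) and `run_record.json`.
#' @param force Overwrite existing image files (default refuse).
#' @param keep_fields Keep the generated `ist_field` objects in the returned
#'   list (defaults to `TRUE` only when not writing to disk; a full default
#'   cohort held in memory is large).
#' @return List with `manifest` (tibble), `truth` (tibble keyed by
#'   `field_id`), `fields` (named list or `NULL`) and `run` (run record).
#' @export
generate_cohort <- function(config, seed = 1L, out_dir = NULL, force = FALSE,
                            keep_fields = is.null(out_dir)) {
  if (inherits(config, "ist_group_spec")) config <- list(config)
  stopifnot(length(config) >= 1L)
  t_start <- Sys.time()
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  ages <- sort(unique(vapply(config, `[[`, integer(1), "age_months")))
  batch_by_age <- vapply(ages, function(a) {
    sdlog <- config[[which(vapply(config, `[[`, integer(1),
                                  "age_months") == a)[1]]]$batch_sdlog
    with_stream(seed, "batch", a, code = rlnorm(1, 0, sdlog))
  }, numeric(1))
  names(batch_by_age) <- as.character(ages)

  manifest <- list(); truth <- list(); fields <- list()
  for (spec in config) {
    g <- spec$genotype; a <- spec$age_months
    batch <- batch_by_age[[as.character(a)]]
    for (m in seq_len(spec$n_mice)) {
      mouse_id <- sprintf("m%02d", m)
      mouse_eff <- with_stream(seed, "mouse", g, a, m,
                               code = rlnorm(1, 0, spec$mouse_sdlog))
      for (s in seq_len(spec$slices_per_mouse)) {
        slice_id <- sprintf("s%d", s)
        bleach <- with_stream(seed, "bleach", g, a, m, s,
                              code = rlnorm(1, 0, spec$bleach_sdlog))
        for (region in names(spec$fields_per_region)) {
          for (fidx in seq_len(spec$fields_per_region[[region]])) {
            fid <- sprintf("%s_%02dm_%s_%s_%s_f%d", g, a, mouse_id, slice_id,
                           region, fidx)
            fseed <- seed_stream(seed, "field", g, a, m, s, region, fidx)
            out <- generate_field(spec, region = region, seed = fseed,
                                  bleach = bleach, batch = batch,
                                  mouse_effect = mouse_eff,
                                  mouse_id = mouse_id, slice_id = slice_id)
            path <- NA_character_
            if (!is.null(out_dir)) {
              path <- file.path(out_dir, paste0(fid, ".tif"))
              if (file.exists(path) && !force) {
                stop("refusing to overwrite existing image: ", path,
                     " (use force = TRUE)", call. = FALSE)
              }
              write_field(out$field, path)
            }
            manifest[[fid]] <- tibble::tibble(
              field_id = fid, path = path, genotype = g, age_months = a,
              mouse_id = mouse_id, slice_id = slice_id, region = region,
              pixel_size_um = spec$pixel_size_um)
            tr <- out$truth
            tr$field_id <- fid
            truth[[fid]] <- tr
            if (keep_fields) fields[[fid]] <- out$field
          }
        }
      }
    }
  }
  manifest <- dplyr::bind_rows(manifest)
  truth <- dplyr::bind_rows(truth)
  run <- list(
    seed = as.integer(seed),
    n_fields = nrow(manifest),
    groups = vapply(config, function(s)
      paste0(s$genotype, "_", s$age_months, "m"), character(1)),
    version = as.character(utils::packageVersion("istquant")),
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")),
    out_dir = if (is.null(out_dir)) NA_character_ else out_dir
  )
  if (!is.null(out_dir)) {
    readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
    truth_flat <- dplyr::select(truth, -dplyr::any_of(
      c("microvessel_centers", "microvessel_radii_um", "large_vessels")))
    readr::write_csv(truth_flat, file.path(out_dir, "truth.csv"))
    rois <- vessel_rois(truth)
    if (nrow(rois) > 0L) {
      write_roi_sidecar(rois, file.path(out_dir, "rois.json"))
    }
    jsonlite::write_json(run, file.path(out_dir, "run_record.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  log_msg("generated %d fields across %d groups (%.1f s)",
          nrow(manifest), length(config), run$elapsed_s)
  list(manifest = manifest, truth = truth,
       fields = if (keep_fields) fields else NULL, run = run)
}

#' Vessel ROI polygons from generator ground truth
#'
#' Builds one regular-polygon ROI (default 16 vertices) per large vessel,
#' padded a couple of micrometers beyond the outer ring radius -- the
#' stand-in for the manual whole-vessel selection of the imaging protocol.
#'
#' @param truth Truth tibble from [generate_cohort()] or [generate_field()].
#' @param n_vertices Polygon vertex count.
#' @param pad_um Padding beyond the outer radius, micrometers.
#' @param pixel_size_um Pixel size used to convert the pad to pixels.
#' @return Tibble with `field_id`, `vessel`, and a `polygon` list-column of
#'   n x 2 matrices of 0-based `(x, y)` pixel vertices.
#' @export
vessel_rois <- function(truth, n_vertices = 16L, pad_um = 2,
                        pixel_size_um = 0.25) {
  rows <- list()
  for (i in seq_len(nrow(truth))) {
    lv <- truth$large_vessels[[i]]
    if (is.null(lv) || nrow(lv) == 0L) next
    for (k in seq_len(nrow(lv))) {
      r_px <- (lv$outer_radius_um[k] + pad_um) / pixel_size_um
      th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
      poly <- cbind(x = lv$cx[k] + r_px * cos(th),
                    y = lv$cy[k] + r_px * sin(th))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        field_id = truth$field_id[i], vessel = k, polygon = list(poly))
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(field_id = character(), vessel = integer(),
                          polygon = list()))
  }
  dplyr::bind_rows(rows)
}
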