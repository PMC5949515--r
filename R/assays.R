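#' Absorbance trace for spectrophotometric assays
#'
#' @param time_min Strictly increasing times, minutes (>= 2 points).
#' @param absorbance Absorbance values (AU).
#' @param wavelength_nm Detection wavelength.
#' @param path_cm Optical path length, cm.
#' @param assay_volume_ml,sample_volume_ml Cuvette and sample volumes, mL.
#' @param protein_mg_per_ml Protein concentration of the sample, mg/mL.
#' @return An `ist_trace` list.
#' @export
absorbance_trace <- function(time_min, absorbance, wavelength_nm = NA_real_,
                             path_cm = 1, assay_volume_ml = 1,
                             sample_volume_ml = 0.05,
                             protein_mg_per_ml = 1) {
  if (length(time_min) < 2L || length(time_min) != length(absorbance)) {
    stop("trace needs >= 2 (time, absorbance) pairs", call. = FALSE)
  }
  if (any(diff(time_min) <= 0)) {
    stop("time points must be strictly increasing", call. = FALSE)
  }
  if (path_cm <= 0 || assay_volume_ml <= 0 || sample_volume_ml <= 0) {
    stop("path length and volumes must be > 0", call. = FALSE)
  }
  structure(list(
    data = tibble::tibble(time_min = time_min, absorbance = absorbance),
    wavelength_nm = wavelength_nm, path_cm = path_cm,
    assay_volume_ml = assay_volume_ml, sample_volume_ml = sample_volume_ml,
    protein_mg_per_ml = protein_mg_per_ml), class = "ist_trace")
}

trace_slope <- function(trace, t_max = Inf) {
  d <- trace$data[trace$data$time_min <= t_max, , drop = FALSE]
  if (nrow(d) < 2L) d <- trace$data[1:2, , drop = FALSE]  # coarse sampling
  s <- unname(coef(lm(absorbance ~ time_min, data = d))[2])
  if (abs(s) < 1e-9) s <- 0  # numerically flat trace
  s
}

assay_result <- function(assay, value, units, ...) {
  tibble::tibble(assay = assay, value = value, units = units, ...)
}

#' Glutathione reductase activity from an A340 trace
#'
#' NADPH consumption is followed at 340 nm; the Beer-Lambert rate is
#' `|slope| / (epsilon * path)` with the molar extinction coefficient
#' 6.22e3 / M / cm, then scaled by the assay-to-sample volume ratio and the
#' protein concentration. Both the raw cuvette rate and the volume-scaled
#' activity are reported (the reported unit, mmol NADPH oxidized per minute
#' per mg protein, leaves the volume referencing open).
#'
#' @param trace An [absorbance_trace()].
#' @param epsilon Molar extinction coefficient of NADPH at 340 nm, 1/(M cm).
#' @return One-row result tibble (`value` = activity, with `rate_uM_per_min`
#'   and `rate_M_per_min` columns alongside).
#' @export
gr_activity <- function(trace, epsilon = 6.22e3) {
  slope <- trace_slope(trace)
  if (slope > 1e-9) {
    stop("A340 increases over time: NADPH is not being consumed ",
         "(invalid trace)", call. = FALSE)
  }
  rate_m <- abs(min(slope, 0)) / (epsilon * trace$path_cm)   # M/min
  rate_mM <- rate_m * 1e3
  activity <- rate_mM * (trace$assay_volume_ml / trace$sample_volume_ml) /
    trace$protein_mg_per_ml
  assay_result("glutathione_reductase", activity,
               "mmol NADPH min^-1 mg^-1",
               rate_M_per_min = rate_m, rate_uM_per_min = rate_m * 1e6,
               slope_AU_per_min = slope, epsilon = epsilon,
               path_cm = trace$path_cm)
}

#' Catalase activity from an A240 trace
#'
#' H2O2 decomposition is followed at 240 nm over a 3-minute window; the
#' activity is the initial-rate slope converted via Beer-Lambert
#' (default epsilon 43.6 / M / cm, configurable) and expressed as micromoles
#' of H2O2 consumed per minute per mg protein.
#'
#' @param trace An [absorbance_trace()].
#' @param epsilon_h2o2 Extinction coefficient of H2O2 at 240 nm, 1/(M cm).
#' @param initial_window_min Initial-rate window, minutes.
#' @return One-row result tibble.
#' @export
catalase_activity <- function(trace, epsilon_h2o2 = 43.6,
                              initial_window_min = 0.5) {
  slope <- trace_slope(trace, t_max = trace$data$time_min[1] +
                         initial_window_min)
  if (slope > 1e-9) {
    stop("A240 increases over the initial window (invalid decay trace)",
         call. = FALSE)
  }
  rate_m <- abs(min(slope, 0)) / (epsilon_h2o2 * trace$path_cm)  # M/min
  rate_um <- rate_m * 1e6
  activity <- rate_um * (trace$assay_volume_ml / trace$sample_volume_ml) /
    trace$protein_mg_per_ml
  assay_result("catalase", activity, "umol H2O2 min^-1 mg^-1",
               rate_M_per_min = rate_m, rate_uM_per_min = rate_um,
               slope_AU_per_min = slope, epsilon = epsilon_h2o2,
               path_cm = trace$path_cm)
}

#' Superoxide dismutase units from epinephrine auto-oxidation rates
#'
#' One unit is the amount of enzyme inhibiting epinephrine oxidation by 50%;
#' units interpolate linearly in percent inhibition
#' (`units = %inhibition / 50`). A sample rate above the control rate gives
#' negative inhibition: reported with a warning, activity floored at 0.
#'
#' @param v_control_rate,v_sample_rate Auto-oxidation rates (AU/min) without
#'   and with sample.
#' @param sample_protein_mg Protein in the cuvette, mg.
#' @return One-row result tibble (`value` = U/mg, `units_in_cuvette`,
#'   `percent_inhibition` alongside).
#' @export
sod_units <- function(v_control_rate, v_sample_rate, sample_protein_mg) {
  if (v_control_rate <= 0) stop("control rate must be > 0", call. = FALSE)
  if (sample_protein_mg <= 0) stop("protein must be > 0", call. = FALSE)
  inhibition <- 100 * (1 - v_sample_rate / v_control_rate)
  if (inhibition < 0) {
    warning(sprintf(
      "sample rate exceeds control rate (inhibition %.1f%%); activity floored at 0",
      inhibition), call. = FALSE)
  }
  units_cuvette <- max(inhibition, 0) / 50
  assay_result("superoxide_dismutase", units_cuvette / sample_protein_mg,
               "U mg^-1", units_in_cuvette = units_cuvette,
               percent_inhibition = inhibition)
}

#' Glutathione peroxidase activity from Ellman readouts
#'
#' GSH consumption over the incubation, per minute and per mg protein.
#'
#' @param gsh_before_uM,gsh_after_uM Reduced-glutathione concentrations (uM)
#'   before and after incubation.
#' @param incubation_min Incubation time, minutes (5 in the standard
#'   protocol).
#' @param protein_mg Protein, mg.
#' @return One-row result tibble.
#' @export
gpx_activity <- function(gsh_before_uM, gsh_after_uM, incubation_min = 5,
                         protein_mg = 1) {
  if (gsh_after_uM > gsh_before_uM) {
    stop("GSH increased during incubation: non-enzymatic artifact ",
         "(after > before)", call. = FALSE)
  }
  if (incubation_min <= 0 || protein_mg <= 0) {
    stop("incubation time and protein must be > 0", call. = FALSE)
  }
  assay_result("glutathione_peroxidase",
               (gsh_before_uM - gsh_after_uM) / incubation_min / protein_mg,
               "uM GSH min^-1 mg^-1",
               gsh_before_uM = gsh_before_uM, gsh_after_uM = gsh_after_uM)
}

#' Thiol concentration from Ellman's reaction (A412)
#'
#' Beer-Lambert with the TNB chromophore (default epsilon 14,150 / M / cm).
#'
#' @param a412 Absorbance at 412 nm (>= 0).
#' @param epsilon_dtnb Extinction coefficient, 1/(M cm).
#' @param path_cm Path length, cm.
#' @return Concentration in micromolar.
#' @export
ellman_concentration <- function(a412, epsilon_dtnb = 14150, path_cm = 1) {
  if (any(a412 < 0)) stop("absorbance must be >= 0", call. = FALSE)
  a412 / (epsilon_dtnb * path_cm) * 1e6
}

#' Redox couple ratio (GSH/GSSG, NADPH/NADP)
#'
#' @param reduced,oxidized Measured amounts of the reduced and oxidized
#'   species (same units).
#' @return One-row tibble with `value` (reduced/oxidized) and `flagged`
#'   (`TRUE`, with `value = NA`, when the oxidized amount is not positive).
#' @export
redox_ratio <- function(reduced, oxidized) {
  if (oxidized <= 0) {
    return(tibble::tibble(value = NA_real_, flagged = TRUE))
  }
  tibble::tibble(value = reduced / oxidized, flagged = FALSE)
}

#' Gel-lane intensity profile
#'
#' @param intensity Non-negative 1-D intensity profile along the lane.
#' @param band_window Integer `c(start, end)` indices of the quantified band.
#' @param loading_reference Positive per-lane loading-control scalar.
#' @return An `ist_lane` list.
#' @export
lane_profile <- function(intensity, band_window, loading_reference = 1) {
  if (any(intensity < 0)) stop("profile must be non-negative", call. = FALSE)
  band_window <- as.integer(band_window)
  if (length(band_window) != 2L || band_window[1] < 1L ||
      band_window[2] > length(intensity) || band_window[1] > band_window[2]) {
    stop("band_window must lie within the profile", call. = FALSE)
  }
  if (loading_reference <= 0) {
    stop("loading_reference must be > 0", call. = FALSE)
  }
  structure(list(intensity = as.numeric(intensity),
                 band_window = band_window,
                 loading_reference = loading_reference),
            class = "ist_lane")
}

#' Background-subtracted, loading-normalized band intensity of one lane
#'
#' The baseline is a rolling minimum over a window three times the band
#' width; the band intensity is the integral of the baseline-subtracted
#' profile over the band window, divided by the lane's loading reference.
#' Adding a constant offset to the profile leaves the result unchanged.
#'
#' @param lane An [lane_profile()].
#' @return Scalar band intensity (a.u.).
#' @export
band_intensity <- function(lane) {
  stopifnot(inherits(lane, "ist_lane"))
  w <- lane$band_window
  width <- w[2] - w[1] + 1L
  k <- min(3L * width, length(lane$intensity))
  if (k %% 2L == 0L) k <- k - 1L
  baseline <- lane_baseline(lane$intensity, k)
  signal <- pmax(lane$intensity - baseline, 0)
  sum(signal[w[1]:w[2]]) / lane$loading_reference
}

# Rolling-minimum baseline. Light smoothing precedes the minimum filter: the
# running minimum of a raw noisy profile sits ~1.5 sd below the true
# background, inflating small bands; a 5-point mean removes most of that bias
# and leaves the baseline equivariant under constant offsets.
#' @keywords internal
lane_baseline <- function(intensity, k) {
  smooth <- zoo::rollapply(intensity, min(5L, k), mean, partial = TRUE)
  zoo::rollapply(smooth, k, min, partial = TRUE)
}

#' Densitometric fold change between two lanes
#'
#' @param case_lane,control_lane [lane_profile()] objects with their band
#'   windows set.
#' @return Scalar fold change (case / control band intensity).
#' @export
band_fold_change <- function(case_lane, control_lane) {
  num <- band_intensity(case_lane)
  den <- band_intensity(control_lane)
  if (den <= 0) stop("control band intensity is zero", call. = FALSE)
  num / den
}

#' Synthetic gel-lane profile with a Gaussian band
#'
#' @param amplitude Band peak amplitude above background.
#' @param center,width_sd Band center index and Gaussian s.d. (positions).
#' @param background Constant background level.
#' @param n Profile length.
#' @param noise_sd Additive Gaussian noise s.d.
#' @param loading_reference Loading-control scalar.
#' @param seed Integer seed.
#' @return An [lane_profile()] with the band window set to center +/- 3 s.d.
#' @export
synth_lane_profile <- function(amplitude, center = 200, width_sd = 12,
                               background = 50, n = 400, noise_sd = 0.5,
                               loading_reference = 1, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    x <- seq_len(n)
    y <- background + amplitude * exp(-(x - center)^2 / (2 * width_sd^2)) +
      rnorm(n, 0, noise_sd)
    lane_profile(pmax(y, 0),
                 c(max(1, round(center - 3 * width_sd)),
                   min(n, round(center + 3 * width_sd))),
                 loading_reference)
  })
}

#' Protein concentration from a Bradford standard curve
#'
#' Ordinary least-squares line through the BSA standards; the unknown is
#' interpolated and flagged when its absorbance lies outside the standards'
#' range (extrapolation).
#'
#' @param standards Data frame with columns `conc` and `absorbance`
#'   (>= 3 non-degenerate standards).
#' @param unknown_absorbance Absorbance of the unknown.
#' @return One-row tibble: `concentration`, `extrapolated`, `slope`,
#'   `intercept`, `r_squared`.
#' @export
protein_standard_curve <- function(standards, unknown_absorbance) {
  if (nrow(standards) < 3L) stop("need >= 3 standards", call. = FALSE)
  if (var(standards$conc) == 0) {
    stop("degenerate standards: identical concentrations", call. = FALSE)
  }
  fit <- lm(absorbance ~ conc, data = standards)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  if (slope == 0) stop("flat standard curve", call. = FALSE)
  conc <- (unknown_absorbance - intercept) / slope
  extrapolated <- unknown_absorbance < min(standards$absorbance) ||
    unknown_absorbance > max(standards$absorbance)
  if (extrapolated) {
    warning("unknown absorbance outside the standards' range: extrapolating",
            call. = FALSE)
  }
  ss_tot <- sum((standards$absorbance - mean(standards$absorbance))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  tibble::tibble(concentration = conc, extrapolated = extrapolated,
                 slope = slope, intercept = intercept, r_squared = r2)
}
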