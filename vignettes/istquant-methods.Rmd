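---
title: "Methods: quantifying immuno-spin-trapping fluorescence in cardiac tissue"
author: "istquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying immuno-spin-trapping fluorescence in cardiac tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Immuno-spin trapping (IST) localizes oxidative macromolecular damage: DMPO
injected in vivo forms stable nitrone adducts at protein/lipid radical
sites, detected ex vivo with an anti-DMPO antibody. In heart sections the
readout is a triple-channel fluorescence field — Hoechst (nuclei), FITC
(cardiomyocyte autofluorescence plus lectin-stained endothelium), Cy3
(DMPO adducts) — and the scientific questions are *where* (cardiomyocytes,
large coronary endothelium, capillaries) and *how much* oxidative
modification accumulates across genotype and age.

Raw Cy3 intensity is not comparable across fields: fluorophores bleach,
and specimens fixed for different durations (older groups wait longer
before batch staining) acquire multiplicative processing effects.
`istquant` therefore implements a two-stage normalization:

1. **Autofluorescence ratio.** Every DMPO score is a ratio of mean Cy3 to
   mean FITC. Both channels share the multiplicative bleaching/batch
   factor, so it cancels. For vessel scores the FITC reference is the mean
   over the field *excluding* vessel masks: lectin-positive endothelium is
   several-fold brighter than tissue autofluorescence and would otherwise
   inflate the denominator. For the cardiomyocyte score the whole field is
   used — vessels cover only a few percent of area (the cohorts here are
   configured at medians of 2.8% for controls and 3.1% for the transgenic
   groups), so whole-field means are effectively cardiomyocyte means.
2. **Age-matched control normalization.** Case scores are divided by the
   median score of the same-age control group. Since both genotypes of an
   age are processed on the same day, a per-age batch factor scales both
   groups equally and cancels exactly; a control group normalized to
   itself has median exactly 1.

Both invariances are enforced by tests: all three compartment scores move
by less than 1% under joint FITC/Cy3 rescaling with factors in [0.25, 2].

## Segmentation conventions

**Otsu threshold.** The threshold maximizes between-class variance on a
256-bin histogram of the in-ROI pixels, bins spanning the in-ROI min–max
range linearly (the ImageJ 8-bit convention). "Dark" polarity: foreground
is the bright class, pixels strictly above the threshold. Ties in the
criterion resolve to the lowest qualifying threshold. The implementation
is checked against an exhaustive search over all 255 cut points.

**Morphological chain.** Capillary detection binarizes the FITC channel at
the Otsu threshold and applies dilation, hole filling, erosion, and
particle analysis. The structuring element is a disk of radius 1 px with
one dilation and one erosion: the literature chain names the operations
but not the element, and a symmetric single pass closes 1–2 px gaps and
fills lumina while leaving isolated object areas essentially unchanged.
Labeling is 8-connected (`EBImage::bwlabel`'s 4-connected labels are
merged across diagonal adjacencies). Particles are retained with areas in
5–300 µm²; large-vessel rings hole-fill into discs of thousands of µm² and
fall out of the capillary count through the upper cutoff. Border-touching
objects are counted — for uniformly placed capillaries of these sizes,
excluding them would bias density downward. Density is retained-object
count divided by field area (counts/mm²).

A field with no lectin-positive structures has a unimodal FITC histogram,
where Otsu simply splits the noise. Detection therefore additionally
requires the foreground/background mean-intensity contrast to reach 2.5
(lectin is ~5× brighter than tissue in the generator's default
configuration, and similar in stained sections); below that the field
reports zero vessels and a zero area fraction rather than noise objects.

**Large vessels.** Vessel ROIs are polygon selections (here produced from
the generator's ground truth, or a JSON sidecar for real data — vessel
selection is manual in the emulated protocol, and no automatic large-vessel
detector is attempted). Within the ROI, Otsu on the in-ROI FITC pixels
yields the endothelial ring mask, which is transferred onto Cy3 for the
score. Vessel radius is the equivalent-circle radius of the hole-filled
ring, `sqrt(area/π) · pixel size`; on generator vessels with radii
≥ 20 µm the per-vessel error is below 2%, so the estimate is dominated by
the configured radius distribution, not the estimator.

**Per-field thresholds.** Otsu is computed per field (and per ROI), never
globally across a batch: the normalizations assume per-field multiplicative
nuisance factors, which per-field thresholds absorb automatically.

## Score definitions and open choices

* Cardiomyocyte: `mean(Cy3)/mean(FITC)` over the field.
* Large-vessel endothelium: `mean(Cy3 | ring) / mean(FITC | tissue)`. A
  mean over the ring mask already accounts for ring area, so no further
  area division is applied by default; the ring area is recorded in the
  score record and `extra_area_norm = TRUE` divides once more for users
  who read the "normalized to endothelial area" convention literally.
* Microvessel: `[mean(Cy3 | lectin⁺ microvessel pixels) / mean(FITC |
  tissue)] / density`. Taken literally, dividing by counts/mm² gives the
  score units of mm²; the values are treated as arbitrary units, as only
  ratios across groups matter.
* Fields with no detected microvessels yield a *flagged, undefined* score
  and are excluded from summaries — zero-filling would drag group medians
  toward zero as capillary loss progresses, conflating density with
  per-vessel intensity.
* Group statistics run at the sampling unit of the corresponding figure
  conventions (fields or vessels, not mouse means); summaries are medians
  with Q1–Q3 (type-7 linear-interpolation quantiles, the spreadsheet
  default; the convention is not otherwise pinned down).

## The statistical decision tree

Two-group comparisons follow a distribution-adaptive tree: Student's
pooled-variance t only when both groups pass Shapiro–Wilk (p > α) *and* a
two-sided F variance-ratio test passes (p > α); otherwise Mann–Whitney.
Choices worth recording:

* For two groups the variance gate is the F test; Bartlett's test is the
  ≥3-group analogue and is not used here.
* No Welch correction: variance heterogeneity routes to Mann–Whitney
  instead.
* Mann–Whitney is exact (full enumeration of all group assignments,
  midranks for ties) when min(n) ≤ 8, and otherwise uses the tie-corrected
  normal approximation *without* continuity correction — so that the
  two-group Kruskal–Wallis χ²(1) equals z² exactly, a property the tests
  assert.
* Groups with n < 3 (below Shapiro–Wilk's minimum) go straight to
  Mann–Whitney with a note in the decision path. Zero-variance t input
  falls back to Mann–Whitney with a warning.
* Monte-Carlo calibration (5,000 replicates per shape, n = 20 per group)
  keeps the tree's type-I error at 0.05 ± 0.01 under both Gaussian and
  log-normal nulls.

Progression across ≥3 ordered groups uses Kruskal–Wallis (tie-corrected)
with Dunn's rank-based pairwise z post hoc. Dunn p-values are
Bonferroni-adjusted by default with a `"none"` option, since the emulated
protocol does not state an adjustment. The parametric branch is one-way
ANOVA with Fisher LSD (unadjusted pairwise t on the residual mean square —
unadjusted by definition of LSD), and a two-way genotype×age ANOVA with
type-II sums of squares for unbalanced layouts. Linear trends over ordered
groups use the equally spaced contrast on group means with the one-way
ANOVA error mean square; a shuffled-label calibration check keeps its null
rejection rate at 5%. Significance stars map p < 0.05/0.01/0.005/0.001 to
`*`/`**`/`***`/`****`.

## Assay calculators

All spectrophotometric activities are Beer–Lambert conversions of fitted
absorbance slopes. ε(NADPH, 340 nm) = 6.22×10³ M⁻¹cm⁻¹ is the stated
coefficient for glutathione reductase; ε(H₂O₂, 240 nm) = 43.6 M⁻¹cm⁻¹ and
ε(TNB, 412 nm) = 14,150 M⁻¹cm⁻¹ are defaults taken from the classical
Aebi and Ellman methods (conventional values for these assays) and are
config-overridable. Catalase uses an initial-rate window (default 30 s) of
the decay trace; when sampling is too coarse for the window the first two
points define the slope. The GR unit ("mmol NADPH oxidized per minute per
mg protein") leaves cuvette-vs-sample volume referencing ambiguous, so
both the raw cuvette rate and the volume-scaled activity are reported.
SOD units interpolate linearly in percent inhibition around the defining
50% point (1 U); negative inhibition floors at zero with a warning.

Lane densitometry integrates the baseline-subtracted profile over the band
window and divides by a per-lane loading reference; fold change is the
case/control ratio. The baseline is a rolling minimum over a window three
times the band width, computed on a lightly smoothed profile (5-point
mean): the running minimum of a raw noisy trace sits ~1.5σ below the true
background and would inflate small bands relative to large ones. Constant
offsets added to a lane cancel exactly.

## The synthetic cohort generator

No imaging data are deposited for this kind of study, so the package
ships a generator that emulates the *statistical structure* the analysis
assumes, with full ground truth:

* **Sampling design.** Two genotypes × ages 8–16 months; per mouse, 2
  slices; per slice, 3 fields each of left ventricle, right ventricle and
  septum plus 1 papillary field. Default group sizes follow the IST arm
  of the emulated study (4–6 mice/group).
* **Geometry.** 1024×1024 px fields at 0.25 µm/px (0.0655 mm²) — chosen so
  a median large vessel and ~130 capillaries fit one field; no camera
  resolution is published. Capillaries are non-touching lectin discs; base
  radii are drawn uniformly on 1.5–2.5 µm and rescaled per field
  (clamped to 1.4–4.5 µm) so the painted lectin-positive area matches the
  field's target fraction drawn from a log-normal. The area-fraction
  log-normals (medians 2.8%/3.1%) have spreads fitted from reported
  quartiles as `mean(|ln(Q3/med)|, |ln(med/Q1)|)/0.6745` — reported
  quartiles are mildly asymmetric and this symmetrizes in log space. The
  1.4 µm lower clamp keeps every capillary above the 5 µm² particle
  filter; capillary lumens at these radii sit at the resolution limit,
  so capillaries are filled discs (rings are used for large vessels,
  whose 2–5 µm endothelial annuli the morph chain must hole-fill).
* **Large vessels.** Outer ring radii are log-normal with median 42.9 µm
  and sdlog 0.558 (fitted from the reported 27.5–58.4 µm quartiles).
  Dedicated vessel fields are 1280 px so that draws are almost never
  truncated by the border (<2% tail) and the measured median stays
  unbiased; standard fields default to zero large vessels.
* **Intensities.** Arbitrary units by construction (no absolute
  calibration is published): tissue autofluorescence 1,500 a.u. with a
  ±12% smooth texture, lectin 8,000 a.u., control DMPO levels ~1,000–1,200
  a.u., additive Gaussian noise σ = 150 a.u. per channel. Default Tg
  effects are configuration values (normalized figures publish no absolute
  intensities): DMPO ratios rising with age in all compartments, steepest
  at 16 months; capillary density 2,000/mm² in controls at all ages
  (the gradual control-strain loss is reported as non-significant and is
  not quantified) declining to 1,000/mm² in 16-month Tg groups — a 50%
  configured loss.
* **Nuisances.** Per-slice bleach factor ~ logN(0, 0.15), per-age batch
  factor ~ logN(0, 0.2) shared by both genotypes of that age (same-day
  processing), per-mouse DMPO random effect ~ logN(0, 0.15). These exist
  solely to exercise the normalizations.
* **Reproducibility.** One root seed; per-entity streams derive from a
  stable string hash of (group, mouse, slice, region, index), so cohorts
  are bit-reproducible and insensitive to generation order.

What the generator does **not** emulate: optical point-spread functions
(vessel edges are crisp, so segmentation accuracy on synthetic fields is
an upper bound), 3-D sectioning effects, fibrosis/hypertrophy morphology,
spatially varying staining, or autofluorescence spectra. Passing recovery
tests therefore demonstrates the pipeline's correctness and its
invariances — not that real tissue achieves the same accuracy.

## Numerical choices and degenerate inputs

* Constant images/ROIs have no Otsu threshold and raise a degenerate-input
  error; whole-field conveniences (`vessel_area_fraction`,
  `detect_microvessels`) treat constant fields as vessel-free instead.
* Otsu criterion ties return the lowest threshold; `which.max` on the
  vectorized criterion guarantees it.
* Identical constant groups: Kruskal–Wallis reports H = 0, p = 1, flagged
  degenerate; one-way ANOVA reports F = 0.
* All-tied Mann–Whitney (zero tie-corrected variance) reports p = 1.
* 16-bit clipping: nuisance application rounds and clips to [0, 65535];
  invariance tolerances (1%) absorb the integer rounding.
* Pixel coordinates are 0-based (x, y) with origin top-left; areas in µm²
  via pixel_size²; densities per mm².

## Problem sizes

The test suite validates most operations on 256–512 px fields (fast,
~8–35 capillaries each) and freezes oracle values computed by brute force.
The recovery checks use the full default conditions: ≥200 fields per
genotype for area-fraction medians, 150–160 vessels for the radius median,
50–60 fields per density configuration, 5,000 Monte-Carlo replicates per
null shape for the decision-tree calibration. These sizes put the
sampling error of each recovered quantity well inside its stated
tolerance band while keeping a full run in the minutes range on one core.

## Known limitations

* No automatic large-vessel detection: ROIs must be supplied (or come from
  generator truth).
* The Hoechst channel is generated and carried for visualization only;
  no nuclear segmentation is performed.
* The microvessel score's literal units (mm²) follow from the stated
  definition; values are comparable only within a processing convention.
* Proprietary microscope formats (CZI/LIF) and OME-XML are out of scope;
  fields are plain multi-page 16-bit TIFFs with resolution tags.
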