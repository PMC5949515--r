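test_that("cardiomyocyte score is the Cy3/FITC whole-field ratio", {
  f <- const_field(fitc = 1000, cy3 = 1000)
  expect_identical(cardiomyocyte_score(f)$score, 1)
  f2 <- const_field(fitc = 1000, cy3 = 2000)
  expect_identical(cardiomyocyte_score(f2)$score, 2)
  f3 <- const_field(fitc = 0, cy3 = 10)
  expect_error(cardiomyocyte_score(f3), "zero mean FITC")
})

test_that("scores are invariant under joint multiplicative rescaling", {
  out <- generate_field(tiny_spec(field_px = 512L), seed = 8L,
                        bleach = 1, batch = 1)
  f <- out$field
  scaled <- apply_nuisance(f, 0.6, 1)
  expect_lt(abs(cardiomyocyte_score(scaled)$score /
                  cardiomyocyte_score(f)$score - 1), 0.01)
  det <- detect_microvessels(f)
  det_s <- detect_microvessels(scaled)
  m1 <- microvessel_score(f, det)
  m2 <- microvessel_score(scaled, det_s)
  expect_lt(abs(m2$score / m1$score - 1), 0.01)
})

test_that("vessel endothelium score normalizes ring Cy3 by tissue FITC", {
  n <- 64
  fitc <- matrix(1000L, n, n)
  cy3 <- matrix(500L, n, n)
  ring <- disc_into(matrix(FALSE, n, n), 32, 32, 12, TRUE) &
    !disc_into(matrix(FALSE, n, n), 32, 32, 9, TRUE)
  fitc[ring] <- 8000L
  cy3[ring] <- 3000L
  f <- ist_field(matrix(300L, n, n), fitc, cy3, 1)
  rec <- vessel_endothelium_score(f, ring)
  expect_equal(rec$score, 3, tolerance = 1e-9)
  expect_equal(rec$auxiliary, sum(ring) * 1, tolerance = 1e-9)  # area um^2
  expect_error(vessel_endothelium_score(f, matrix(FALSE, n, n)), "empty")
  # optional extra area normalization divides once more by ring area
  rec2 <- vessel_endothelium_score(f, ring, extra_area_norm = TRUE)
  expect_equal(rec2$score, 3 / sum(ring), tolerance = 1e-9)
})

test_that("endothelial effect sizes are recovered over many vessels", {
  specs <- list(ctrl = vessel_field_spec("control", 8),
                tg = vessel_field_spec("control", 8))
  specs$tg$dmpo_level["large_vessel_endothelium"] <-
    2 * specs$ctrl$dmpo_level[["large_vessel_endothelium"]]
  med <- lapply(specs, function(sp) {
    vapply(1:15, function(s) {
      out <- generate_field(sp, seed = 300L + s)
      out$truth$field_id <- "f"
      ring <- segment_endothelial_ring(out$field,
                                       vessel_rois(out$truth)$polygon[[1]])
      vessel_endothelium_score(out$field, ring)$score
    }, numeric(1))
  })
  expect_lt(abs(median(med$tg) / median(med$ctrl) - 2), 0.2)
})

test_that("microvessel score arithmetic and undefined flagging", {
  n <- 64
  fitc <- matrix(1000L, n, n)
  cy3 <- matrix(400L, n, n)
  disc <- disc_into(matrix(FALSE, n, n), 20, 20, 5, TRUE)
  fitc[disc] <- 8000L
  cy3[disc] <- 2000L
  f <- ist_field(matrix(300L, n, n), fitc, cy3, 1)
  labels <- matrix(0L, n, n); labels[disc] <- 1L
  fake_objects <- structure(list(labels = labels,
                                 objects = tibble::tibble(id = 1L),
                                 pixel_size_um = 1), class = "ist_objects")
  rec <- microvessel_score(f, fake_objects, density = 2000)
  expect_equal(rec$score, (2000 / 1000) / 2000, tolerance = 1e-9)

  rec0 <- microvessel_score(f, fake_objects, density = 0)
  expect_true(rec0$flagged)
  expect_true(is.na(rec0$score))
})

test_that("halving density doubles the microvessel score", {
  sp_hi <- tiny_spec(field_px = 512L, microvessel_density_true = 2000)
  sp_lo <- tiny_spec(field_px = 512L, microvessel_density_true = 1000)
  score_of <- function(sp, seeds) {
    vapply(seeds, function(s) {
      out <- generate_field(sp, seed = s, bleach = 1, batch = 1)
      microvessel_score(out$field, detect_microvessels(out$field))$score
    }, numeric(1))
  }
  hi <- mean(score_of(sp_hi, 1:10))
  lo <- mean(score_of(sp_lo, 11:20))
  expect_lt(abs(lo / hi - 2), 0.25)
})

test_that("microvessel density is count over area", {
  expect_identical(microvessel_density(20, 0.01), 2000)
  expect_identical(microvessel_density(0, 0.5), 0)
  expect_error(microvessel_density(5, 0), "> 0")
})

test_that("vessel area fraction measures painted discs", {
  n <- 100
  fitc <- matrix(1000L, n, n)
  r <- sqrt(0.01 * n * n / pi)  # 1% of the field
  disc <- disc_into(matrix(FALSE, n, n), 50, 50, r, TRUE)
  fitc[disc] <- 8000L
  f <- ist_field(matrix(300L, n, n), fitc, matrix(500L, n, n), 0.25)
  expect_lt(abs(vessel_area_fraction(f) - 0.01), 2 * pi * r / (n * n))
  expect_identical(vessel_area_fraction(const_field()), 0)
})

test_that("control normalization has the stated algebra", {
  expect_identical(normalize_to_control(c(2, 4, 6), c(1, 1, 3)), c(2, 4, 6))
  ctrl <- c(0.8, 1.3, 2.1, 1.7, 0.9)
  expect_identical(median(normalize_to_control(ctrl, ctrl)), 1)
  expect_error(normalize_to_control(1:3, numeric(0)), "empty control")
  expect_error(normalize_to_control(1:3, c(-2, -1, 0)), "> 0")
  # scaling an age's scores by c > 0 cancels (to floating-point rounding)
  case <- c(1.2, 2.5, 3.1); ctl <- c(0.9, 1.1, 1.4)
  expect_equal(normalize_to_control(case * 3.7, ctl * 3.7),
               normalize_to_control(case, ctl), tolerance = 1e-12)
})

test_that("batch factors shared across genotypes cancel in normalized scores", {
  base <- tiny_spec(field_px = 512L)
  tg <- tiny_spec("Tg", field_px = 512L)
  tg$dmpo_level[] <- tg$dmpo_level * 1.5
  score_set <- function(sp, batch, seeds) {
    vapply(seeds, function(s) {
      out <- generate_field(sp, seed = s, bleach = 1, batch = batch)
      cardiomyocyte_score(out$field)$score
    }, numeric(1))
  }
  for (batch in c(1, 1.6)) {
    ctl <- score_set(base, batch, 1:6)
    cas <- score_set(tg, batch, 7:12)
    norm <- normalize_to_control(cas, ctl)
    if (batch == 1) ref_norm <- norm
  }
  expect_true(all(abs(norm / ref_norm - 1) < 0.01))
})

test_that("group summaries use type-7 quantiles", {
  s <- summarize_group(c(1, 2, 3, 4, 5))
  expect_identical(s$median, 3)
  expect_identical(s$q1, 2)
  expect_identical(s$q3, 4)
  s1 <- summarize_group(7)
  expect_true(all(unlist(s1[c("median", "q1", "q3")]) == 7))
  withr::with_seed(13, {
    x <- rlnorm(37)
    s2 <- summarize_group(x)
    expect_equal(s2$median, quantile7_oracle(x, 0.5), tolerance = 1e-12)
    expect_equal(s2$q1, quantile7_oracle(x, 0.25), tolerance = 1e-12)
    expect_equal(s2$q3, quantile7_oracle(x, 0.75), tolerance = 1e-12)
  })
})

test_that("raising the endothelial DMPO level raises the median score", {
  meds <- vapply(c(1000, 2000, 4000), function(level) {
    sp <- vessel_field_spec()
    sp$dmpo_level["large_vessel_endothelium"] <- level
    median(vapply(1:8, function(s) {
      out <- generate_field(sp, seed = 400L + s)
      out$truth$field_id <- "f"
      ring <- segment_endothelial_ring(out$field,
                                       vessel_rois(out$truth)$polygon[[1]])
      vessel_endothelium_score(out$field, ring)$score
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
})
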