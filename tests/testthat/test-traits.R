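# Analytic oracles: a digital disk of radius r has area ~ pi r^2, roundness
# ~ 1, eccentricity ~ 0; an axis-aligned digital ellipse with semi-axes a,b
# has moment axis lengths 2a/2b, lwr a/b and eccentricity sqrt(1-(b/a)^2).

test_that("disk morphology matches the circle formulas", {
  m <- labeled_mask(disk_mask(120, c(60, 60), 50))
  rec <- measure_morphology(m, scale_calibration(0.1))
  expect_true(rec$valid)
  expect_lt(abs(rec$area_mm2 - pi * 25) / (pi * 25), 0.02)  # 78.54 mm2 at s=0.1
  expect_gt(rec$roundness, 0.95)
  expect_lte(rec$roundness, 1.05)
  expect_lt(rec$eccentricity, 0.15)
  expect_gte(rec$convex_area_mm2, rec$area_mm2)
})

test_that("ellipse morphology matches the closed-form axis ratios", {
  m <- labeled_mask(ellipse_mask(160, c(80, 80), 60, 30))
  rec <- measure_morphology(m, scale_calibration(1))
  expect_lt(abs(rec$lwr - 2) / 2, 0.02)
  expect_lt(abs(rec$eccentricity - sqrt(0.75)) / sqrt(0.75), 0.02)
  expect_lt(abs(rec$length_mm - 120) / 120, 0.02)
  expect_lt(abs(rec$width_mm - 60) / 60, 0.02)
})

test_that("degenerate and tiny objects are flagged invalid", {
  lab <- matrix(0L, 40, 40)
  lab[20, 5:35] <- 1L  # 1-px line
  rec <- measure_morphology(labeled_mask(lab), scale_calibration(1))
  expect_false(rec$valid)

  lab2 <- matrix(0L, 20, 20); lab2[10, 10:12] <- 1L  # < 10 px
  rec2 <- measure_morphology(labeled_mask(lab2), scale_calibration(1))
  expect_false(rec2$valid)
})

test_that("spectral means are exact for painted constants and honor masking", {
  lab <- disk_mask(60, c(30, 30), 15)
  m <- labeled_mask(lab)
  px <- array(0.05, dim = c(60, 60, 2))
  half <- col(lab) <= 30
  px[, , 1] <- ifelse(half, 0.2, 0.6)  # 525 nm: half 0.2 / half 0.6
  px[, , 2] <- matrix(0.42, 60, 60)    # 780 nm: painted constant
  stack <- msi_stack(px, c(525, 780))
  sp <- measure_spectral(m, stack)
  expect_equal(sp$refl_780, 0.42)
  expect_lt(abs(sp$refl_525 - 0.4), 0.01)  # one-pixel parity tolerance
  vp <- matrix(as.integer(half), 60, 60)
  sp2 <- measure_spectral(m, stack, valid_pixels = vp)
  expect_equal(sp2$refl_525, 0.2)
  # a label with no valid pixels warns and yields NA
  expect_warning(sp3 <- measure_spectral(m, stack,
                                         valid_pixels = 0 * vp), "no valid")
  expect_true(is.na(sp3$refl_525))
})

test_that("measure_lot joins records and excludes invalid seeds from the summary", {
  lab <- disk_mask(100, c(30, 30), 20)
  lab[80, 80:82] <- 1L  # would merge labels; keep as separate tiny object
  lab2 <- matrix(0L, 100, 100)
  lab2[lab == 1L & row(lab) < 60] <- 1L
  lab2[80, 80:82] <- 2L
  stack <- msi_stack(array(0.5, dim = c(100, 100, 1)), 780)
  lot <- measure_lot(stack, labeled_mask(lab2), scale_calibration(0.1))
  expect_identical(nrow(lot$records), 2L)
  expect_identical(lot$n_valid, 1L)
  expect_true(all(lot$summary$n[lot$summary$trait == "area_mm2"] == 1))

  empty <- measure_lot(stack, labeled_mask(matrix(0L, 100, 100)),
                       scale_calibration(0.1))
  expect_identical(nrow(empty$records), 0L)
  expect_identical(empty$n_valid, 0L)
})

test_that("scale estimation is a plain ratio with guarded inputs", {
  expect_equal(estimate_scale(10, 500)$mm_per_pixel, 0.02)
  expect_equal(estimate_scale(1, 1)$mm_per_pixel, 1)
  expect_error(estimate_scale(10, 0), "positive")
  expect_error(estimate_scale(-1, 10), "positive")
})

test_that("traits scale equivariantly with mm_per_pixel", {
  m <- labeled_mask(ellipse_mask(140, c(70, 70), 50, 25, angle = 0.4))
  r1 <- measure_morphology(m, scale_calibration(0.05))
  r2 <- measure_morphology(m, scale_calibration(0.10))
  expect_equal(r2$length_mm, 2 * r1$length_mm)
  expect_equal(r2$width_mm, 2 * r1$width_mm)
  expect_equal(r2$perimeter_mm, 2 * r1$perimeter_mm)
  expect_equal(r2$area_mm2, 4 * r1$area_mm2)
  expect_equal(r2$convex_area_mm2, 4 * r1$convex_area_mm2)
  expect_equal(r2$lwr, r1$lwr)
  expect_equal(r2$eccentricity, r1$eccentricity)
  expect_equal(r2$roundness, r1$roundness)
  expect_equal(r1$lwr * r1$width_mm, r1$length_mm, tolerance = 1e-9)
})

test_that("elongating an ellipse raises lwr and eccentricity, lowers roundness", {
  prev <- NULL
  for (a in c(30, 40, 50)) {
    m <- labeled_mask(ellipse_mask(140, c(70, 70), a, 20))
    r <- measure_morphology(m, scale_calibration(1))
    if (!is.null(prev)) {
      expect_gt(r$lwr, prev$lwr)
      expect_gt(r$eccentricity, prev$eccentricity)
      expect_lt(r$roundness, prev$roundness)
    }
    prev <- r
  }
})

test_that("spectral means are invariant under seed relabeling", {
  lab <- matrix(0L, 80, 80)
  lab[disk_mask(80, c(25, 25), 12) == 1L] <- 1L
  lab[disk_mask(80, c(55, 55), 12) == 1L] <- 2L
  px <- array(0, dim = c(80, 80, 1))
  px[, , 1] <- ifelse(lab == 1L, 0.3, ifelse(lab == 2L, 0.7, 0.05))
  stack <- msi_stack(px, 780)
  sp <- measure_spectral(labeled_mask(lab), stack)
  swapped <- lab; swapped[lab == 1L] <- 2L; swapped[lab == 2L] <- 1L
  sp2 <- measure_spectral(labeled_mask(swapped), stack)
  expect_setequal(sp$refl_780, sp2$refl_780)
})

test_that("the band-substance table lists the eight key bands", {
  bs <- band_substance_map()
  expect_identical(bs$wavelength_nm,
                   c(375L, 450L, 525L, 630L, 645L, 660L, 940L, 970L))
  expect_identical(bs$substance[bs$wavelength_nm == 970L], "water")
  expect_identical(bs$substance[bs$wavelength_nm == 375L], "crude protein")
})
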