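# The dark-red a* fixture: sRGB (0.75, 0.08, 0.10) converts to a* ~ 62.4
# (checked against grDevices::convertColor), above the fixed threshold of 45,
# while neutral gray sits at a* ~ 0.

test_that("neutral images produce no overexposure detections", {
  rgb <- flat_rgb(60)
  expect_true(all(detect_overexposed(rgb) == 0L))
  expect_true(all(detect_overexposed(rgb, overexposure_params("fixed")) == 0L))
})

test_that("a saturated dark-red patch is flagged exactly in fixed mode", {
  patch <- list(rows = 21:40, cols = 26:45)
  rgb <- flat_rgb(60, patch = patch)
  a <- srgb_to_lab(rgb$pixels)[, , 2]
  expect_gt(a[30, 30], 45)           # the dark-red a* clears the threshold
  expect_lt(abs(a[5, 5]), 1)         # gray stays near 0
  m <- detect_overexposed(rgb, overexposure_params("fixed"))
  want <- matrix(0L, 60, 60); want[patch$rows, patch$cols] <- 1L
  expect_identical(m, want)
})

test_that("flagged regions below min_region_px are discarded", {
  rgb <- flat_rgb(40, patch = list(rows = 10:10, cols = 10:12))  # 3 px
  m <- detect_overexposed(rgb, overexposure_params("fixed", min_region_px = 5))
  expect_true(all(m == 0L))
})

test_that("overexposure params validate their fields", {
  expect_error(overexposure_params(adaptive_window_px = 50), "odd")
  expect_error(overexposure_params(min_region_px = 0), "min_region_px")
})

test_that("calibration is a no-op for an empty overexposure mask", {
  rgb <- flat_rgb(40, base = c(0.45, 0.30, 0.20))
  z <- matrix(0L, 40, 40)
  fg <- matrix(1L, 40, 40)
  out <- calibrate_overexposed(rgb, z, fg)
  expect_identical(out$pixels, rgb$pixels)
})

test_that("saturated cores are rebuilt from the same seed's exposed pixels", {
  size <- 80
  seed <- disk_mask(size, c(40, 40), 25)
  core <- disk_mask(size, c(40, 40), 8)
  px <- array(rep(c(0.10, 0.20, 0.55), each = size * size),
              dim = c(size, size, 3))
  seed_col <- c(0.45, 0.30, 0.20); core_col <- c(0.9, 0.1, 0.1)
  for (ch in 1:3) {
    p <- px[, , ch]
    p[seed == 1L] <- seed_col[ch]
    p[core == 1L] <- core_col[ch]
    px[, , ch] <- p
  }
  rgb <- rgb_image(px)
  set.seed(11)
  out <- calibrate_overexposed(rgb, core, seed)
  for (ch in 1:3) {
    repl <- out$pixels[, , ch][core == 1L]
    expect_lt(abs(mean(repl) - seed_col[ch]), 0.02)
  }
  # pixels outside the flagged mask are untouched
  for (ch in 1:3)
    expect_identical(out$pixels[, , ch][core == 0L], px[, , ch][core == 0L])
  # second-pass detection inside the seed foreground is empty (idempotence)
  second <- detect_overexposed(out, overexposure_params("fixed"))
  expect_true(all((second & seed) == 0))
})

test_that("flagged regions outside the seed foreground stay unchanged", {
  rgb <- flat_rgb(40, patch = list(rows = 5:10, cols = 5:10))
  oe <- matrix(0L, 40, 40); oe[5:10, 5:10] <- 1L
  fg <- matrix(0L, 40, 40); fg[25:35, 25:35] <- 1L
  out <- calibrate_overexposed(rgb, oe, fg)
  expect_identical(out$pixels, rgb$pixels)
})

test_that("an all-flagged seed object is left unchanged with a warning", {
  rgb <- flat_rgb(30, patch = list(rows = 10:20, cols = 10:20))
  oe <- matrix(0L, 30, 30); oe[10:20, 10:20] <- 1L
  fg <- oe
  expect_warning(out <- calibrate_overexposed(rgb, oe, fg),
                 "no properly exposed")
  expect_identical(out$pixels, rgb$pixels)
})

test_that("background removal recovers disk objects near pixel-exactly", {
  size <- 200
  fg_true <- disk_mask(size, c(60, 60), 25) | disk_mask(size, c(140, 140), 30)
  stack <- flat_stack(fg_true)
  got <- remove_background(stack, background_params(adaptive_window_px = 101))
  expect_true(all(got %in% c(0L, 1L)))
  # disagreement confined to a <= 1 px boundary ring
  dm_in <- EBImage::distmap(matrix(as.numeric(fg_true), size, size))
  dm_out <- EBImage::distmap(matrix(as.numeric(!fg_true), size, size))
  ring <- dm_in <= 1 | dm_out <= 1
  expect_true(all((got == fg_true) | ring))
})

test_that("a constant reference band yields an empty mask", {
  stack <- msi_stack(array(0.3, dim = c(50, 50, 1)), 780)
  expect_true(all(remove_background(stack) == 0L))
})

test_that("interior holes are filled and small objects removed", {
  size <- 150
  fg <- disk_mask(size, c(75, 75), 30)
  hole <- disk_mask(size, c(75, 75), 3)  # 10-px scale interior hole
  speck <- disk_mask(size, c(20, 20), 2) # below min_object_px
  stack <- flat_stack((fg & !hole) | speck)
  got <- remove_background(stack, background_params(adaptive_window_px = 101))
  expect_true(all(got[hole == 1L] == 1L))
  expect_true(all(got[speck == 1L & fg == 0L] == 0L))
  got2 <- remove_background(stack,
                            background_params(adaptive_window_px = 101,
                                              fill_holes = FALSE))
  expect_true(all(got2[disk_mask(size, c(75, 75), 1) == 1L] == 0L))
})
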