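test_that("watershed keeps a single disk as one label", {
  fg <- disk_mask(120, c(60, 60), 40)
  m <- watershed_refine(fg)
  expect_identical(m$n_seeds, 1L)
  expect_true(all((m$labels > 0L) == (fg > 0L)))
})

test_that("watershed splits overlapping disks near the perpendicular bisector", {
  # centers (60,90) and (120,90): the analytic split line is row 90
  fg <- disk_mask(180, c(60, 90), 40) | disk_mask(180, c(120, 90), 40)
  m <- watershed_refine(matrix(as.integer(fg), 180, 180))
  expect_identical(m$n_seeds, 2L)
  pts <- which(m$labels > 0L, arr.ind = TRUE)
  lab_of <- m$labels[pts]
  top <- lab_of[pts[, 1] <= 88]; bottom <- lab_of[pts[, 1] >= 92]
  expect_identical(length(unique(top)), 1L)
  expect_identical(length(unique(bottom)), 1L)
  expect_false(unique(top) == unique(bottom))
})

test_that("watershed discards components below min_seed_area_px", {
  fg <- disk_mask(60, c(30, 30), 6.8)  # ~145 px
  expect_lt(sum(fg), 200)
  m <- watershed_refine(fg)
  expect_identical(m$n_seeds, 0L)
  m2 <- watershed_refine(matrix(0L, 40, 40))
  expect_identical(m2$n_seeds, 0L)
})

test_that("edge smoothing leaves a clean digital ellipse untouched", {
  lab <- ellipse_mask(160, c(80, 80), 60, 30)
  m <- smooth_edges(labeled_mask(lab))
  expect_identical(m$labels, lab)
})

test_that("edge smoothing repairs a narrow deep notch", {
  lab <- ellipse_mask(160, c(80, 80), 60, 30)
  full_area <- sum(lab)
  notch <- lab
  notch[80, 50:58] <- 0L  # 1 px wide, ~8 px deep, cut inward from the boundary
  notch[81, 50:58] <- 0L
  m <- smooth_edges(labeled_mask(notch))
  expect_identical(m$n_seeds, 1L)
  expect_gt(sum(m$labels > 0L), 0.99 * full_area)
  expect_lt(sum(m$labels > 0L), 1.01 * full_area)
})

test_that("edge smoothing never bleeds labels across adjacent objects", {
  lab <- matrix(0L, 100, 100)
  lab[ellipse_mask(100, c(35, 50), 28, 14) == 1L] <- 1L
  two <- ellipse_mask(100, c(66, 50), 28, 14) == 1L & lab == 0L
  lab[two] <- 2L
  m <- smooth_edges(labeled_mask(lab))
  expect_identical(m$n_seeds, 2L)
  expect_true(all(m$labels[lab == 1L] %in% c(0L, 1L)))
  expect_true(all(m$labels[lab == 2L] %in% c(0L, 2L)))
})

# Context lot: three isolated disks set the lot-median statistics so the
# touching gate (area, solidity) and merge eligibility behave as in a real lot.
with_context_disks <- function(size, extra) {
  lab <- matrix(0L, size, size)
  ctr <- list(c(50, 50), c(50, size - 50), c(size - 50, 50))
  for (i in seq_along(ctr)) lab[disk_mask(size, ctr[[i]], 40) == 1L] <- i
  extra(lab, length(ctr))
}

test_that("touching disk pairs are split into parts near single-disk area", {
  size <- 320
  res <- with_context_disks(size, function(lab, n) {
    pair <- disk_mask(size, c(200, 160), 40) | disk_mask(size, c(270, 160), 40)
    lab[pair == 1L] <- n + 1L
    split_touching(labeled_mask(lab))
  })
  expect_identical(res$n_seeds, 5L)
  disk_area <- sum(disk_mask(320, c(50, 50), 40))
  areas <- sort(tabulate(res$labels[res$labels > 0L], 5L))
  new_parts <- tail(areas, 2)  # all five should in fact be disk-sized
  for (a in areas) expect_lt(abs(a - disk_area) / disk_area, 0.10)
})

test_that("a single convex seed is never split", {
  lab <- ellipse_mask(160, c(80, 80), 60, 30)
  m <- split_touching(labeled_mask(lab))
  expect_identical(m$n_seeds, 1L)
  expect_identical(sum(m$labels > 0L), sum(lab))
})

test_that("defects shallower than the depth gate do not trigger cuts", {
  size <- 320
  res <- with_context_disks(size, function(lab, n) {
    pair <- disk_mask(size, c(200, 160), 40) | disk_mask(size, c(270, 160), 40)
    lab[pair == 1L] <- n + 1L
    # raise the depth gate above this pair's defect depth: nothing may change
    split_touching(labeled_mask(lab),
                   segmentation_params(defect_depth_min_px = 60))
  })
  expect_identical(res$n_seeds, 4L)
})

test_that("a bisected ellipse merges back into the exact original mask", {
  size <- 320
  res <- with_context_disks(size, function(lab, n) {
    ell <- ellipse_mask(size, c(200, 160), 42, 26)
    left <- ell == 1L & row(ell) < 200
    lab[left] <- n + 1L
    lab[ell == 1L & !left] <- n + 2L
    list(merged = merge_oversegmented(labeled_mask(lab)), ell = ell, n = n)
  })
  expect_identical(res$merged$n_seeds, 4L)
  restored <- res$merged$labels == res$merged$labels[200, 160]
  expect_identical(matrix(as.integer(restored), 320, 320), res$ell)
})

test_that("isolated small debris and full-size neighbours are not merged", {
  size <- 320
  res <- with_context_disks(size, function(lab, n) {
    lab[disk_mask(size, c(250, 250), 10) == 1L] <- n + 1L  # isolated debris
    merge_oversegmented(labeled_mask(lab))
  })
  expect_identical(res$n_seeds, 4L)

  # two adjacent full-size seeds: neither is merge-eligible
  lab <- matrix(0L, 140, 140)
  lab[ellipse_mask(140, c(45, 70), 30, 16) == 1L] <- 1L
  two <- ellipse_mask(140, c(78, 70), 30, 16) == 1L & lab == 0L
  lab[two] <- 2L
  m <- merge_oversegmented(labeled_mask(lab))
  expect_identical(m$n_seeds, 2L)
})

test_that("merging never changes the total foreground pixel count", {
  size <- 320
  with_context_disks(size, function(lab, n) {
    ell <- ellipse_mask(size, c(200, 160), 42, 26)
    left <- ell == 1L & row(ell) < 200
    lab[left] <- n + 1L
    lab[ell == 1L & !left] <- n + 2L
    m <- merge_oversegmented(labeled_mask(lab))
    expect_identical(sum(m$labels > 0L), sum(lab > 0L))
    invisible(NULL)
  })
})

test_that("full-lot segmentation recovers the rendered seed count", {
  spec <- scene_spec(image_size_px = 548, n_seeds = 20, rng_seed = 7)
  scn <- render_lot(spec)
  mask <- segment_lot(scn$stack, scn$rgb, verbose = FALSE)
  expect_identical(mask$n_seeds, scn$truth$mask$n_seeds)
  expect_gt(mean_iou(mask, scn$truth$mask)$miou, 0.95)
  expect_true(!is.null(attr(mask, "valid_pixels")))
})

test_that("an empty scene and a single-seed scene segment correctly", {
  spec0 <- scene_spec(image_size_px = 300, n_seeds = 0, rng_seed = 3)
  scn0 <- render_lot(spec0)
  m0 <- segment_lot(scn0$stack, verbose = FALSE)
  expect_identical(m0$n_seeds, 0L)

  spec1 <- scene_spec(image_size_px = 300, n_seeds = 1, touching_fraction = 0,
                      rng_seed = 3)
  scn1 <- render_lot(spec1)
  m1 <- segment_lot(scn1$stack, verbose = FALSE)
  expect_identical(m1$n_seeds, 1L)
  expect_gte(mean_iou(m1, scn1$truth$mask)$matches$iou[1], 0.95)
})

test_that("every stage preserves label contiguity and single components", {
  spec <- scene_spec(image_size_px = 548, n_seeds = 15, rng_seed = 5)
  scn <- render_lot(spec)
  fg <- remove_background(scn$stack)
  stages <- list(watershed = watershed_refine(fg))
  stages$smoothed <- smooth_edges(stages$watershed)
  stages$split <- split_touching(stages$smoothed)
  stages$merged <- merge_oversegmented(stages$split)
  for (nm in names(stages)) {
    m <- stages[[nm]]
    u <- sort(unique(m$labels[m$labels > 0L]))
    expect_identical(u, seq_len(m$n_seeds), info = nm)
    for (k in u)
      expect_identical(max(seedmsi:::label8(m$labels == k)), 1L,
                       info = sprintf("%s label %d", nm, k))
  }
  # foreground-count discipline: smoothing may only add (bounded), the
  # split stage net change is at most the cut-line pixels
  expect_lte(sum(stages$split$labels > 0L),
             sum(stages$smoothed$labels > 0L) + 200L)
  expect_gte(sum(stages$split$labels > 0L),
             sum(stages$smoothed$labels > 0L) - 200L)
  expect_identical(sum(stages$merged$labels > 0L),
                   sum(stages$split$labels > 0L))
})

test_that("segmentation is deterministic", {
  spec <- scene_spec(image_size_px = 400, n_seeds = 8, rng_seed = 9)
  scn <- render_lot(spec)
  m1 <- segment_lot(scn$stack, scn$rgb, verbose = FALSE)
  m2 <- segment_lot(scn$stack, scn$rgb, verbose = FALSE)
  expect_identical(m1$labels, m2$labels)
})
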