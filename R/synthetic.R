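# Synthetic multispectral seed-lot renderer with exact ground truth.
#
# Seeds are rotated ellipses with smooth low-order radial perturbation
# (bounded at 5% of the minor axis), laid on a blue conveyor-belt background:
# high reflectance around 450 nm, low at the 780 nm reference band, so the
# rendered scenes reproduce the premise that seeds and belt separate at
# 780 nm. Ground-truth labels are rendered before noise and saturation, and
# per-seed traits are computed analytically from the boundary polygons.

default_seed_profile <- function(wl) {
  stats::approx(c(375, 970), c(0.08, 0.55), xout = wl, rule = 2)$y
}

default_belt_profile <- function(wl) {
  stats::approx(c(375, 450, 525, 630, 780, 970),
                c(0.38, 0.45, 0.33, 0.18, 0.05, 0.04), xout = wl, rule = 2)$y
}

#' Scene specification for the synthetic renderer
#'
#' Defaults emulate the acquisition this package targets: 60-80 seeds per
#' lot on a blue belt, ~30% of seeds in touching pairs, ~10% with a saturated
#' dark-red core in the sRGB companion, additive Gaussian sensor noise.
#' Desk-scale scenes are 1096 px (use 2192 for full-scale runs; seed axes are
#' given in pixels and should be scaled with the image).
#'
#' @param image_size_px square scene side (px).
#' @param n_seeds number of seeds; `NULL` draws uniformly from 60-80.
#' @param touching_fraction fraction of seeds placed in touching pairs.
#' @param overexposure_fraction fraction of seeds given a saturated core.
#' @param seed_shape list: `major_mean`, `major_sd`, `minor_mean`, `minor_sd`
#'   (semi-axis px); rotation is uniform on `[0, pi)`.
#' @param reflectance_profile list: `seed_mean` and `belt_mean` (per band),
#'   `seed_sd` (between-seed per-band sd), `belt_sd` (per-lot belt offset sd),
#'   `brightness_sd` (sd of the per-seed brightness factor).
#' @param noise_sd additive Gaussian sensor noise sd.
#' @param mm_per_px physical scale of the scene.
#' @param wavelengths_nm band set.
#' @param rng_seed integer RNG seed; rendering is deterministic given it.
#' @export
scene_spec <- function(image_size_px = 1096L,
                       n_seeds = NULL,
                       touching_fraction = 0.3,
                       overexposure_fraction = 0.1,
                       seed_shape = list(major_mean = 38, major_sd = 4,
                                         minor_mean = 19, minor_sd = 2),
                       reflectance_profile = NULL,
                       noise_sd = 0.01,
                       mm_per_px = 0.08,
                       wavelengths_nm = VIDEOMETER_WAVELENGTHS,
                       rng_seed = 0L) {
  if (touching_fraction < 0 || touching_fraction > 1 ||
      overexposure_fraction < 0 || overexposure_fraction > 1)
    stop("fractions must lie in [0,1]")
  if (seed_shape$major_mean <= 0 || seed_shape$minor_mean <= 0)
    stop("seed axes must be positive")
  if (is.null(reflectance_profile))
    reflectance_profile <- list(
      seed_mean = default_seed_profile(wavelengths_nm),
      seed_sd = 0.015,
      belt_mean = default_belt_profile(wavelengths_nm),
      belt_sd = 0.005,
      brightness_sd = 0.06)
  i780 <- which.min(abs(wavelengths_nm - 780))
  sep <- abs(reflectance_profile$seed_mean[i780] -
               reflectance_profile$belt_mean[i780])
  if (sep < 3 * noise_sd)
    stop("seed and belt reflectance at the reference band must be separated ",
         "by at least 3 x noise_sd")
  structure(list(image_size_px = as.integer(image_size_px), n_seeds = n_seeds,
                 touching_fraction = touching_fraction,
                 overexposure_fraction = overexposure_fraction,
                 seed_shape = seed_shape,
                 reflectance_profile = reflectance_profile,
                 noise_sd = noise_sd, mm_per_px = mm_per_px,
                 wavelengths_nm = as.integer(wavelengths_nm),
                 rng_seed = as.integer(rng_seed)),
            class = "scene_spec")
}

# Analytic morphology of a closed boundary polygon (px units).
polygon_morphology <- function(x, y) {
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  A <- sum(cr) / 2
  s <- sign(A); A <- abs(A)
  cx <- sum((x + x2) * cr) / (6 * A) * s
  cy <- sum((y + y2) * cr) / (6 * A) * s
  ixx <- sum((x^2 + x * x2 + x2^2) * cr) / 12 * s
  iyy <- sum((y^2 + y * y2 + y2^2) * cr) / 12 * s
  ixy <- sum((x * y2 + 2 * x * y + 2 * x2 * y2 + x2 * y) * cr) / 24 * s
  cxx <- ixx / A - cx^2; cyy <- iyy / A - cy^2; cxy <- ixy / A - cx * cy
  ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2), symmetric = TRUE,
              only.values = TRUE)$values
  ev <- pmax(ev, 0)
  per <- sum(sqrt((x2 - x)^2 + (y2 - y)^2))
  h <- grDevices::chull(x, y)
  hx <- x[h]; hy <- y[h]
  conv <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy) / 2)
  list(area = A, convex_area = conv, length = 4 * sqrt(ev[1]),
       width = 4 * sqrt(ev[2]), perimeter = per)
}

#' Render a synthetic seed lot
#'
#' @param spec a [scene_spec()].
#' @return list with `stack` ([msi_stack()]), `rgb` ([rgb_image()]) and
#'   `truth`: a list holding `mask` ([labeled_mask()], rendered before noise),
#'   `traits` (analytic per-seed trait table, mm units, plus the drawn
#'   per-band mean reflectances), `touching_pairs` (two-column matrix of label
#'   pairs) and `overexposed_seeds`.
#' @export
render_lot <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_rng_seed(spec$rng_seed, render_lot_impl(spec))
}

render_lot_impl <- function(spec) {
  sz <- spec$image_size_px
  shp <- spec$seed_shape
  n <- if (is.null(spec$n_seeds)) sample(60:80, 1L) else as.integer(spec$n_seeds)
  nb <- length(spec$wavelengths_nm)
  th <- seq(0, 2 * pi, length.out = 513L)[-513L]

  if (n == 0L) return(render_empty_scene(spec))
  # per-seed geometry
  a <- pmax(rnorm(n, shp$major_mean, shp$major_sd), 4)
  b <- pmax(rnorm(n, shp$minor_mean, shp$minor_sd), 2)
  swap <- b > a
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  rot <- runif(n, 0, pi)
  rtab <- matrix(0, length(th), max(n, 1L))
  amp <- numeric(n)
  for (i in seq_len(n)) {
    raw <- rep(0, length(th))
    for (k in 2:6) raw <- raw + rnorm(1) * cos(k * th) + rnorm(1) * sin(k * th)
    amp[i] <- runif(1, 0.01, 0.05) * b[i]
    pert <- if (max(abs(raw)) > 0) raw / max(abs(raw)) * amp[i] else raw
    rell <- a[i] * b[i] / sqrt((b[i] * cos(th))^2 + (a[i] * sin(th))^2)
    rtab[, i] <- rell + pert
  }
  rmax <- if (n > 0L) apply(rtab, 2, max) else numeric(0)

  # placement: touching pairs first, then singles
  n_pairs <- round(spec$touching_fraction * n / 2)
  centers <- matrix(NA_real_, n, 2)
  placed <- integer(0)
  radius_at <- function(i, phi) {
    # boundary radius of seed i along world direction phi
    t0 <- (phi - rot[i]) %% (2 * pi)
    stats::approx(c(th, 2 * pi), c(rtab[, i], rtab[1, i]), xout = t0)$y
  }
  clear_of_placed <- function(p, i, skip = integer(0)) {
    for (k in setdiff(placed, skip)) {
      if (sqrt(sum((p - centers[k, ])^2)) <= rmax[i] + rmax[k] + 3) return(FALSE)
    }
    TRUE
  }
  rand_center <- function(i) {
    m <- rmax[i] + 6
    c(runif(1, m, sz - m), runif(1, m, sz - m))
  }
  place_pair <- function(i, j) {
    for (try in 1:400) {
      p1 <- rand_center(i)
      phi <- runif(1, 0, 2 * pi)
      delta <- runif(1, 0.10, 0.25) * mean(c(b[i], b[j]))
      d <- radius_at(i, phi) + radius_at(j, phi + pi) - delta
      p2 <- p1 + d * c(cos(phi), sin(phi))
      m2 <- rmax[j] + 6
      if (p2[1] < m2 || p2[1] > sz - m2 || p2[2] < m2 || p2[2] > sz - m2) next
      if (!clear_of_placed(p1, i) || !clear_of_placed(p2, j)) next
      centers[i, ] <<- p1; centers[j, ] <<- p2
      placed <<- c(placed, i, j)
      return(TRUE)
    }
    FALSE
  }
  place_single <- function(i) {
    for (try in 1:400) {
      p <- rand_center(i)
      if (clear_of_placed(p, i)) {
        centers[i, ] <<- p; placed <<- c(placed, i)
        return(TRUE)
      }
    }
    FALSE
  }
  pairs <- if (n_pairs > 0) matrix(seq_len(2 * n_pairs), ncol = 2, byrow = TRUE)
  else matrix(integer(0), ncol = 2)
  for (p in seq_len(n_pairs))
    if (!place_pair(pairs[p, 1], pairs[p, 2]))
      stop("infeasible packing: could not place touching pair ", p)
  for (i in setdiff(seq_len(n), as.vector(pairs)))
    if (!place_single(i))
      stop("infeasible packing: could not place seed ", i)

  # rasterize: contested pixels go to the seed with smaller normalized radius
  lab <- matrix(0L, sz, sz)
  ndbuf <- matrix(Inf, sz, sz)
  for (i in seq_len(n)) {
    cr <- centers[i, 1]; cc <- centers[i, 2]
    r1 <- max(1L, floor(cr - rmax[i] - 2)); r2 <- min(sz, ceiling(cr + rmax[i] + 2))
    c1 <- max(1L, floor(cc - rmax[i] - 2)); c2 <- min(sz, ceiling(cc + rmax[i] + 2))
    dx <- (r1:r2) - cr; dy <- (c1:c2) - cc
    u <- outer(dx, dy * 0, "+") * cos(rot[i]) + outer(dx * 0, dy, "+") * sin(rot[i])
    v <- -outer(dx, dy * 0, "+") * sin(rot[i]) + outer(dx * 0, dy, "+") * cos(rot[i])
    t0 <- atan2(v, u) %% (2 * pi)
    ri <- matrix(stats::approx(c(th, 2 * pi), c(rtab[, i], rtab[1, i]),
                               xout = as.vector(t0))$y, nrow(u), ncol(u))
    nd <- sqrt(u^2 + v^2) / ri
    subnd <- ndbuf[r1:r2, c1:c2]
    sublab <- lab[r1:r2, c1:c2]
    take <- nd <= 1 & nd < subnd
    sublab[take] <- i
    subnd[take] <- nd[take]
    lab[r1:r2, c1:c2] <- sublab
    ndbuf[r1:r2, c1:c2] <- subnd
  }

  # analytic ground-truth morphology from the boundary polygons
  s <- spec$mm_per_px
  traits <- do.call(rbind, lapply(seq_len(n), function(i) {
    bx <- centers[i, 1] + rtab[, i] * cos(th) * cos(rot[i]) -
      rtab[, i] * sin(th) * sin(rot[i])
    by <- centers[i, 2] + rtab[, i] * cos(th) * sin(rot[i]) +
      rtab[, i] * sin(th) * cos(rot[i])
    pm <- polygon_morphology(bx, by)
    data.frame(seed_id = i,
               area_mm2 = pm$area * s^2, convex_area_mm2 = pm$convex_area * s^2,
               length_mm = pm$length * s, width_mm = pm$width * s,
               perimeter_mm = pm$perimeter * s,
               lwr = pm$length / pm$width,
               eccentricity = sqrt(max(0, 1 - (pm$width / pm$length)^2)),
               roundness = min(4 * pi * pm$area / pm$perimeter^2, 1.05))
  }))

  # spectral truth: per-seed per-band mean reflectance
  prof <- spec$reflectance_profile
  bf <- rnorm(n, 1, prof$brightness_sd)
  belt_off <- rnorm(1, 0, prof$belt_sd)
  belt_val <- pmin(pmax(prof$belt_mean + belt_off, 0.01), 0.97)
  seed_val <- matrix(0, n, nb)
  for (j in seq_len(nb))
    seed_val[, j] <- pmin(pmax(prof$seed_mean[j] * bf +
                                 rnorm(n, 0, prof$seed_sd), 0.02), 0.98)
  if (n > 0L) {
    refl <- as.data.frame(seed_val)
    names(refl) <- paste0("refl_", spec$wavelengths_nm)
    traits <- cbind(traits, refl)
  }

  # render bands: tissue mean + noise, clipped
  px <- array(0, dim = c(sz, sz, nb))
  labv <- as.vector(lab)
  for (j in seq_len(nb)) {
    lut <- c(belt_val[j], seed_val[, j])
    px[, , j] <- pmin(pmax(lut[labv + 1L] + rnorm(sz * sz, 0, spec$noise_sd),
                           0), 1)
  }

  # sRGB companion: brown seeds on a blue belt, saturated dark-red cores
  n_oe <- round(spec$overexposure_fraction * n)
  oe_seeds <- if (n_oe > 0) sort(sample(seq_len(n), n_oe)) else integer(0)
  belt_rgb <- c(0.10, 0.20, 0.55)
  seed_rgb <- c(0.45, 0.30, 0.20)
  core_rgb <- c(0.85, 0.08, 0.10)
  rgbpx <- array(0, dim = c(sz, sz, 3))
  core <- matrix(FALSE, sz, sz)
  for (i in oe_seeds) core <- core | (lab == i & ndbuf <= 0.45)
  for (ch in 1:3) {
    lut <- c(belt_rgb[ch], pmin(pmax(seed_rgb[ch] * bf, 0.02), 0.98))
    m <- matrix(lut[labv + 1L], sz, sz)
    m[core] <- core_rgb[ch]
    rgbpx[, , ch] <- pmin(pmax(m + rnorm(sz * sz, 0, spec$noise_sd), 0), 1)
  }

  lot_id <- sprintf("synthetic_lot_seed%d", spec$rng_seed)
  truth_traits <- cbind(data.frame(lot_id = rep(lot_id, n)), traits)
  list(stack = msi_stack(px, spec$wavelengths_nm, lot_id),
       rgb = rgb_image(rgbpx, lot_id),
       truth = list(mask = labeled_mask(lab),
                    traits = truth_traits,
                    touching_pairs = pairs,
                    overexposed_seeds = oe_seeds))
}

# Empty scene: belt only, no seeds.
render_empty_scene <- function(spec) {
  sz <- spec$image_size_px
  nb <- length(spec$wavelengths_nm)
  prof <- spec$reflectance_profile
  belt_val <- pmin(pmax(prof$belt_mean + rnorm(1, 0, prof$belt_sd), 0.01), 0.97)
  px <- array(0, dim = c(sz, sz, nb))
  for (j in seq_len(nb))
    px[, , j] <- pmin(pmax(belt_val[j] + rnorm(sz * sz, 0, spec$noise_sd), 0), 1)
  rgbpx <- array(0, dim = c(sz, sz, 3))
  belt_rgb <- c(0.10, 0.20, 0.55)
  for (ch in 1:3)
    rgbpx[, , ch] <- pmin(pmax(belt_rgb[ch] + rnorm(sz * sz, 0, spec$noise_sd), 0), 1)
  lot_id <- sprintf("synthetic_lot_seed%d", spec$rng_seed)
  list(stack = msi_stack(px, spec$wavelengths_nm, lot_id),
       rgb = rgb_image(rgbpx, lot_id),
       truth = list(mask = labeled_mask(matrix(0L, sz, sz)),
                    traits = NULL,
                    touching_pairs = matrix(integer(0), ncol = 2),
                    overexposed_seeds = integer(0)))
}

#' Generate a replicated population of scene specifications
#'
#' Genotype effects are drawn once per genotype (variance `sigma2_g`) and
#' lot-level residuals per replicate (variance `sigma2_e`); both are applied
#' to the trait-controlling seed length, yielding one [scene_spec()] per lot
#' plus the true effects for recovery testing.
#'
#' @param n_genotypes,reps_per_genotype design size (reps >= 1).
#' @param sigma2_g,sigma2_e genetic and residual variances (trait units^2).
#' @param base_trait_means list with `length_mm`, the population-mean seed
#'   length the effects act on.
#' @param rng_seed integer seed.
#' @param spec_template a [scene_spec()] supplying all other scene settings.
#' @return list: `phenotypes` (data frame `genotype`, `rep`, `value`),
#'   `genotype_effects` (true effects), `specs` (list of per-lot
#'   [scene_spec()]s).
#' @export
render_population <- function(n_genotypes, reps_per_genotype,
                              sigma2_g, sigma2_e,
                              base_trait_means = list(length_mm = 6.2),
                              rng_seed = 0L,
                              spec_template = scene_spec()) {
  stopifnot(sigma2_g >= 0, sigma2_e >= 0, reps_per_genotype >= 1,
            n_genotypes >= 1)
  with_rng_seed(rng_seed, {
    g <- rnorm(n_genotypes, 0, sqrt(sigma2_g))
    ph <- expand.grid(rep = seq_len(reps_per_genotype),
                      genotype = seq_len(n_genotypes))[, 2:1]
    ph$value <- base_trait_means$length_mm + g[ph$genotype] +
      rnorm(nrow(ph), 0, sqrt(sigma2_e))
    specs <- lapply(seq_len(nrow(ph)), function(i) {
      sp <- spec_template
      # seed length (mm) -> semi-major axis (px); keep aspect ratio
      ratio <- sp$seed_shape$minor_mean / sp$seed_shape$major_mean
      sp$seed_shape$major_mean <- max(ph$value[i] / 2 / sp$mm_per_px, 4)
      sp$seed_shape$minor_mean <- sp$seed_shape$major_mean * ratio
      sp$rng_seed <- rng_seed + i
      sp
    })
    list(phenotypes = ph, genotype_effects = g, specs = specs)
  })
}
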