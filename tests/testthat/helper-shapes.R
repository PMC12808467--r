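# Geometric fixtures built in code: digital disks, ellipses, and small
# synthetic stacks used across the unit tests.

disk_mask <- function(size, center, r) {
  xy <- expand.grid(seq_len(size), seq_len(size))
  d <- sqrt((xy[, 1] - center[1])^2 + (xy[, 2] - center[2])^2)
  matrix(as.integer(d <= r), size, size)
}

ellipse_mask <- function(size, center, a, b, angle = 0) {
  xy <- expand.grid(seq_len(size), seq_len(size))
  dx <- xy[, 1] - center[1]; dy <- xy[, 2] - center[2]
  u <- dx * cos(angle) + dy * sin(angle)
  v <- -dx * sin(angle) + dy * cos(angle)
  matrix(as.integer((u / a)^2 + (v / b)^2 <= 1), size, size)
}

# Single-band stack: objects at `fg_value` on a flat belt.
flat_stack <- function(fg, fg_value = 0.55, belt_value = 0.05,
                       wavelength = 780L) {
  px <- matrix(belt_value, nrow(fg), ncol(fg))
  px[fg != 0] <- fg_value
  msi_stack(array(px, dim = c(dim(fg), 1L)), wavelength, "fixture")
}

# Uniform-colour rgb_image with an optional rectangular patch.
flat_rgb <- function(size, base = c(0.5, 0.5, 0.5), patch = NULL,
                     patch_rgb = c(0.75, 0.08, 0.10)) {
  px <- array(rep(base, each = size * size), dim = c(size, size, 3))
  if (!is.null(patch)) {
    for (ch in 1:3) px[patch$rows, patch$cols, ch] <- patch_rgb[ch]
  }
  rgb_image(px)
}
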