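# Pre-processing: overexposure handling on the sRGB companion and removal of
# the blue conveyor-belt background from the reflectance stack.

#' Parameters for overexposure detection
#'
#' Overexposed seed regions show as saturated dark-red pixels; they are found
#' on the a* channel of CIE L*a*b*. In `"adaptive"` mode a pixel is flagged
#' when its a* exceeds the local box mean by `-adaptive_offset` (the offset is
#' subtracted from the local mean, so the default -10 flags pixels 10 a* units
#' above their neighbourhood); in `"fixed"` mode when a* exceeds
#' `fixed_a_star_threshold`.
#'
#' @param a_star_method `"adaptive"` or `"fixed"`.
#' @param adaptive_window_px odd local-mean window side (px).
#' @param adaptive_offset a* units subtracted from the local mean.
#' @param fixed_a_star_threshold absolute a* threshold for `"fixed"` mode.
#' @param min_region_px flagged regions smaller than this are discarded.
#' @export
overexposure_params <- function(a_star_method = c("adaptive", "fixed"),
                                adaptive_window_px = 51L,
                                adaptive_offset = -10,
                                fixed_a_star_threshold = 45,
                                min_region_px = 5L) {
  a_star_method <- match.arg(a_star_method)
  if (adaptive_window_px < 3L || adaptive_window_px %% 2L == 0L)
    stop("adaptive_window_px must be odd and >= 3")
  if (min_region_px < 1L) stop("min_region_px must be >= 1")
  structure(list(a_star_method = a_star_method,
                 adaptive_window_px = as.integer(adaptive_window_px),
                 adaptive_offset = adaptive_offset,
                 fixed_a_star_threshold = fixed_a_star_threshold,
                 min_region_px = as.integer(min_region_px)),
            class = "overexposure_params")
}

#' Parameters for belt-background removal
#'
#' Seeds are separated from the blue conveyor belt on a reference NIR band
#' (default 780 nm) where seeds are bright and the belt is dark, using a local
#' adaptive threshold (box local mean plus `adaptive_offset`).
#'
#' @param reference_wavelength_nm band used for thresholding.
#' @param adaptive_window_px odd local-mean window side (px).
#' @param adaptive_offset reflectance added to the local mean before
#'   thresholding. The default 0.02 keeps belt-only regions (where the local
#'   mean equals the belt level) from flagging sensor noise.
#' @param fill_holes fill enclosed holes inside foreground objects.
#' @param min_object_px foreground components smaller than this are removed.
#' @export
background_params <- function(reference_wavelength_nm = 780L,
                              adaptive_window_px = 201L,
                              adaptive_offset = 0.02,
                              fill_holes = TRUE,
                              min_object_px = 50L) {
  if (adaptive_window_px < 3L || adaptive_window_px %% 2L == 0L)
    stop("adaptive_window_px must be odd and >= 3")
  structure(list(reference_wavelength_nm = as.integer(reference_wavelength_nm),
                 adaptive_window_px = as.integer(adaptive_window_px),
                 adaptive_offset = adaptive_offset,
                 fill_holes = isTRUE(fill_holes),
                 min_object_px = as.integer(min_object_px)),
            class = "background_params")
}

#' Convert an sRGB array to CIE L*a*b* (D65)
#'
#' Standard sRGB transfer and D65 white point, via [grDevices::convertColor()].
#'
#' @param pixels height x width x 3 sRGB array in `[0,1]`.
#' @return height x width x 3 array of L*, a*, b*.
#' @export
srgb_to_lab <- function(pixels) {
  d <- dim(pixels)
  flat <- matrix(pixels, prod(d[1:2]), 3L)
  lab <- grDevices::convertColor(flat, from = "sRGB", to = "Lab")
  array(lab, dim = d)
}

#' Detect overexposed (saturated dark-red) pixels
#'
#' @param rgb an [rgb_image()].
#' @param params an [overexposure_params()].
#' @return binary integer matrix (1 = overexposed).
#' @export
detect_overexposed <- function(rgb, params = overexposure_params()) {
  stopifnot(inherits(rgb, "rgb_image"))
  a <- srgb_to_lab(rgb$pixels)[, , 2]
  flag <- if (params$a_star_method == "fixed") {
    a > params$fixed_a_star_threshold
  } else {
    a > box_mean(a, params$adaptive_window_px) - params$adaptive_offset
  }
  lab <- label8(matrix(as.integer(flag), nrow(a), ncol(a)))
  lab <- drop_small(lab, params$min_region_px)
  matrix(as.integer(lab > 0L), nrow(a), ncol(a))
}

#' Calibrate overexposed seed regions
#'
#' Each flagged pixel inside the seed foreground is replaced by the
#' per-channel median of the properly exposed pixels of the *same* 8-connected
#' seed object, plus small zero-mean Gaussian jitter (sd = that object's
#' properly exposed per-channel sd, capped at 0.02) to avoid flat artifacts.
#' Pixels outside the flagged mask, and flagged pixels outside the seed
#' foreground, are never modified. Deterministic given the caller's RNG state.
#'
#' @param rgb an [rgb_image()].
#' @param overexposed binary matrix from [detect_overexposed()].
#' @param seed_foreground binary matrix of seed pixels (belt excluded), e.g.
#'   from [remove_background()].
#' @return a calibrated [rgb_image()].
#' @export
calibrate_overexposed <- function(rgb, overexposed, seed_foreground) {
  stopifnot(inherits(rgb, "rgb_image"))
  d <- dim(rgb$pixels)
  if (!all(dim(overexposed) == d[1:2]) || !all(dim(seed_foreground) == d[1:2]))
    stop("masks must match the image shape")
  px <- rgb$pixels
  obj <- label8(seed_foreground)
  flagged <- overexposed != 0 & obj > 0L
  if (!any(flagged)) return(rgb)
  for (k in sort(unique(obj[flagged]))) {
    sel_obj <- obj == k
    sel_bad <- sel_obj & flagged
    sel_ok <- sel_obj & !flagged
    if (!any(sel_ok)) {
      warning("seed object ", k,
              " has no properly exposed pixels; left unchanged")
      next
    }
    nbad <- sum(sel_bad)
    for (ch in 1:3) {
      v <- px[, , ch][sel_ok]
      jit <- if (length(v) > 1L) rnorm(nbad, 0, min(sd(v), 0.02)) else rep(0, nbad)
      p <- px[, , ch]
      p[sel_bad] <- pmin(pmax(median(v) + jit, 0), 1)
      px[, , ch] <- p
    }
  }
  rgb_image(px, rgb$lot_id)
}

#' Remove the blue conveyor-belt background
#'
#' Local adaptive threshold on the reference band (seeds brighter than the
#' belt), optional hole filling, and small-object removal. When the reference
#' band is essentially constant (global sd < 1e-6) an empty mask is returned
#' rather than thresholding noise.
#'
#' @param stack an [msi_stack()].
#' @param params a [background_params()].
#' @return binary integer matrix (1 = seed foreground), the initial seed mask
#'   consumed by [watershed_refine()].
#' @export
remove_background <- function(stack, params = background_params()) {
  stopifnot(inherits(stack, "msi_stack"))
  band <- stack_band(stack, params$reference_wavelength_nm)
  if (sd(band) < 1e-6)
    return(matrix(0L, nrow(band), ncol(band)))
  fg <- band > box_mean(band, params$adaptive_window_px) + params$adaptive_offset
  fg <- matrix(as.numeric(fg), nrow(band), ncol(band))
  if (params$fill_holes) fg <- EBImage::fillHull(fg)
  lab <- drop_small(label8(fg), params$min_object_px)
  matrix(as.integer(lab > 0L), nrow(band), ncol(band))
}
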