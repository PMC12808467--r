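# Data model and raster/table I/O.
#
# A multispectral stack is a height x width x n_bands reflectance array in
# [0,1] with strictly increasing integer wavelengths (nm). Labeled masks are
# integer matrices with background 0 and seed labels 1..n_seeds, each label a
# single 8-connected component.

# The 19-band VideometerLab4 wavelength set (nm), UV to NIR.
VIDEOMETER_WAVELENGTHS <- c(375L, 405L, 435L, 450L, 470L, 505L, 525L, 570L,
                            590L, 630L, 645L, 660L, 700L, 780L, 850L, 870L,
                            890L, 940L, 970L)

MORPH_COLUMNS <- c("area_mm2", "convex_area_mm2", "length_mm", "width_mm",
                   "perimeter_mm", "lwr", "eccentricity", "roundness")

#' Construct a multispectral stack
#'
#' @param pixels numeric array, height x width x n_bands, reflectance in `[0,1]`.
#' @param wavelengths_nm strictly increasing integer wavelengths, one per band.
#' @param lot_id text identifier of the seed lot.
#' @return an object of class `msi_stack` with elements `pixels`,
#'   `wavelengths_nm`, `lot_id`.
#' @export
msi_stack <- function(pixels, wavelengths_nm, lot_id = "lot") {
  if (length(dim(pixels)) == 2L) dim(pixels) <- c(dim(pixels), 1L)
  stopifnot(length(dim(pixels)) == 3L)
  nb <- dim(pixels)[3]
  wavelengths_nm <- as.integer(wavelengths_nm)
  if (nb < 1L) stop("stack must contain at least one band")
  if (length(wavelengths_nm) != nb)
    stop("wavelengths_nm length (", length(wavelengths_nm),
         ") does not match band count (", nb, ")")
  if (nb > 1L && any(diff(wavelengths_nm) <= 0L))
    stop("wavelengths must be strictly increasing")
  if (!all(is.finite(pixels))) stop("stack contains non-finite pixel values")
  if (min(pixels) < 0 || max(pixels) > 1)
    stop("stack reflectance values must lie in [0,1]")
  structure(list(pixels = pixels, wavelengths_nm = wavelengths_nm,
                 lot_id = as.character(lot_id)),
            class = "msi_stack")
}

#' @export
print.msi_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<msi_stack> lot '%s': %d x %d px, %d bands (%d-%d nm)\n",
              x$lot_id, d[1], d[2], d[3],
              min(x$wavelengths_nm), max(x$wavelengths_nm)))
  invisible(x)
}

# Extract one band as a matrix; errors when the wavelength is absent.
stack_band <- function(stack, wavelength_nm) {
  i <- match(wavelength_nm, stack$wavelengths_nm)
  if (is.na(i)) stop("wavelength ", wavelength_nm, " nm not present in stack")
  stack$pixels[, , i]
}

#' Construct an sRGB companion image
#'
#' @param pixels numeric array height x width x 3 (R,G,B) in `[0,1]`.
#' @param lot_id text identifier.
#' @return object of class `rgb_image`.
#' @export
rgb_image <- function(pixels, lot_id = "lot") {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("rgb image must be height x width x 3")
  if (!all(is.finite(pixels)) || min(pixels) < 0 || max(pixels) > 1)
    stop("rgb values must be finite and in [0,1]")
  structure(list(pixels = pixels, lot_id = as.character(lot_id)),
            class = "rgb_image")
}

#' Construct a labeled per-seed mask
#'
#' Labels must be 0 (background) plus the contiguous integers `1..n_seeds`.
#'
#' @param labels integer matrix.
#' @return object of class `labeled_mask` with `labels` and `n_seeds`.
#' @export
labeled_mask <- function(labels) {
  storage.mode(labels) <- "integer"
  u <- sort(unique(labels[labels > 0L]))
  n <- length(u)
  if (n > 0L && !identical(u, seq_len(n)))
    stop("labels must be the contiguous integers 1..n_seeds")
  if (any(labels < 0L)) stop("negative labels are not allowed")
  structure(list(labels = labels, n_seeds = n), class = "labeled_mask")
}

#' @export
print.labeled_mask <- function(x, ...) {
  cat(sprintf("<labeled_mask> %d x %d px, %d seeds\n",
              nrow(x$labels), ncol(x$labels), x$n_seeds))
  invisible(x)
}

#' Pixel-to-millimetre scale calibration
#'
#' @param mm_per_pixel strictly positive length of one pixel in mm.
#' @return object of class `scale_calibration`.
#' @export
scale_calibration <- function(mm_per_pixel) {
  if (!is.finite(mm_per_pixel) || mm_per_pixel <= 0)
    stop("mm_per_pixel must be strictly positive")
  structure(list(mm_per_pixel = mm_per_pixel), class = "scale_calibration")
}

read_gray_page <- function(p) {
  if (length(dim(p)) == 3L) {
    # collapse a replicated-channel grayscale page
    if (dim(p)[3] >= 3L &&
        max(abs(p[, , 1] - p[, , 2])) < 1e-9 &&
        max(abs(p[, , 1] - p[, , 3])) < 1e-9) p <- p[, , 1]
    else stop("expected a single-channel (grayscale) band image")
  }
  p
}

#' Read a multispectral stack
#'
#' Accepts either a multi-page TIFF (one page per band, ascending wavelength)
#' or a directory of per-band grayscale images named `<wavelength>nm.tif` /
#' `.tiff` / `.png`. Integer pixel types are rescaled to `[0,1]` by the dtype
#' maximum (the behaviour of the underlying readers). For multi-page TIFFs the
#' wavelengths are taken from, in order of precedence: `band_spec`, a sidecar
#' file `<path>.wavelengths.txt` (written by [write_stack()]), or - for a bare
#' 19-page file - the standard VideometerLab4 band set.
#'
#' @param path file or directory.
#' @param band_spec optional integer wavelengths overriding band metadata.
#' @param lot_id lot identifier; defaults to the file/directory base name.
#' @return an [msi_stack()].
#' @export
read_stack <- function(path, band_spec = NULL, lot_id = NULL) {
  if (!file.exists(path)) stop("no such file or directory: ", path)
  if (is.null(lot_id)) lot_id <- sub("\\.[^.]*$", "", basename(path))
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(tif|tiff|png)$", ignore.case = TRUE)
    if (length(files) == 0L) stop("no band images found in ", path)
    m <- regmatches(files, regexec("^([0-9]+)nm\\.(tif|tiff|png)$", files,
                                   ignore.case = TRUE))
    bad <- vapply(m, length, 1L) == 0L
    if (any(bad))
      stop("unparseable band file name(s): ", paste(files[bad], collapse = ", "),
           " (expected <wavelength>nm.tif/.png)")
    wl <- as.integer(vapply(m, `[`, "", 2L))
    o <- order(wl)
    wl <- wl[o]; files <- files[o]
    pages <- lapply(file.path(path, files), function(f) {
      if (grepl("\\.png$", f, ignore.case = TRUE)) read_gray_page(png::readPNG(f))
      else read_gray_page(tiff::readTIFF(f))
    })
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, read_gray_page)
    wl <- NULL
    sidecar <- paste0(path, ".wavelengths.txt")
    if (file.exists(sidecar)) wl <- as.integer(readLines(sidecar, warn = FALSE))
    if (is.null(wl) && is.null(band_spec) &&
        length(pages) == length(VIDEOMETER_WAVELENGTHS))
      wl <- VIDEOMETER_WAVELENGTHS
  }
  if (!is.null(band_spec)) {
    band_spec <- as.integer(band_spec)
    if (length(band_spec) != length(pages))
      stop("band_spec names ", length(band_spec), " bands but ", length(pages),
           " were read")
    wl <- band_spec
  }
  if (is.null(wl))
    stop("wavelengths unknown: supply band_spec or a wavelength sidecar")
  shp <- vapply(pages, dim, integer(2))
  if (any(shp[1, ] != shp[1, 1]) || any(shp[2, ] != shp[2, 1]))
    stop("bands are not co-registered: inconsistent image shapes")
  px <- array(unlist(pages, use.names = FALSE), dim = c(shp[1, 1], shp[2, 1],
                                                        length(pages)))
  msi_stack(pmin(pmax(px, 0), 1), wl, lot_id)
}

#' Write a multispectral stack as a 16-bit multi-page TIFF
#'
#' Band wavelengths are stored in a plain-text sidecar
#' `<path>.wavelengths.txt` so that [read_stack()] can recover them.
#'
#' @param stack an [msi_stack()].
#' @param path output `.tif` path.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "msi_stack"))
  pages <- lapply(seq_along(stack$wavelengths_nm),
                  function(i) stack$pixels[, , i])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "deflate")
  writeLines(as.character(stack$wavelengths_nm),
             paste0(path, ".wavelengths.txt"))
  invisible(path)
}

#' Write / read an sRGB companion image (PNG or TIFF)
#' @param rgb an [rgb_image()].
#' @param path output `.png` or `.tif` path.
#' @export
write_rgb <- function(rgb, path) {
  stopifnot(inherits(rgb, "rgb_image"))
  if (grepl("\\.png$", path, ignore.case = TRUE)) png::writePNG(rgb$pixels, path)
  else tiff::writeTIFF(rgb$pixels, path, bits.per.sample = 16L,
                       compression = "deflate")
  invisible(path)
}

#' @rdname write_rgb
#' @param lot_id lot identifier; defaults to the file base name.
#' @export
read_rgb <- function(path, lot_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(lot_id)) lot_id <- sub("\\.[^.]*$", "", basename(path))
  px <- if (grepl("\\.png$", path, ignore.case = TRUE)) png::readPNG(path)
  else tiff::readTIFF(path)
  if (length(dim(px)) == 3L && dim(px)[3] == 4L) px <- px[, , 1:3]
  rgb_image(px, lot_id)
}

#' Write a labeled mask (lossless)
#'
#' Masks are written as 16-bit single-channel TIFF (label values up to 65534).
#' `.png` paths are also accepted but, with the installed PNG writer being
#' 8-bit, are limited to 255 labels.
#'
#' @param mask a [labeled_mask()].
#' @param path output `.tif` (recommended) or `.png` path.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "labeled_mask"))
  if (mask$n_seeds >= 65535L) stop("label overflow: n_seeds must be < 65,535")
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (mask$n_seeds > 255L)
      stop("PNG masks support at most 255 labels; use a .tif path")
    png::writePNG(mask$labels / 255, path)
  } else {
    tiff::writeTIFF(mask$labels / 65535, path, bits.per.sample = 16L,
                    compression = "deflate")
  }
  invisible(path)
}

#' @rdname write_mask
#' @return [read_mask()] returns a [labeled_mask()]; non-contiguous labels on
#'   disk are renumbered 1..n with a warning.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    m <- png::readPNG(path)
    m <- read_gray_page(m)
    lab <- matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
  } else {
    m <- read_gray_page(tiff::readTIFF(path))
    lab <- matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
  }
  u <- sort(unique(lab[lab > 0L]))
  if (length(u) > 0L && !identical(u, seq_along(u))) {
    warning("non-contiguous labels on read; relabeling 1..n")
    map <- integer(max(u)); map[u] <- seq_along(u)
    lab[lab > 0L] <- map[lab[lab > 0L]]
  }
  labeled_mask(lab)
}

#' Write a per-seed trait table as CSV
#'
#' Fixed column order: `lot_id`, `seed_id`, the eight morphological traits,
#' then `refl_<wavelength>` columns in ascending wavelength.
#'
#' @param records data frame of seed trait records (one row per seed) as
#'   produced by [measure_lot()], or a list of such data frames (e.g. several
#'   lots); list elements whose band columns differ raise an error.
#' @param path output CSV path.
#' @export
write_traits_csv <- function(records, path) {
  if (is.list(records) && !is.data.frame(records)) {
    if (!is.null(records$records)) records <- records$records
    else {
      bands <- lapply(records, function(r) grep("^refl_[0-9]+$", names(r), value = TRUE))
      if (length(unique(lapply(bands, sort))) > 1L)
        stop("heterogeneous band sets across records")
      records <- do.call(rbind, records)
    }
  }
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("records must be a non-empty data frame of seed trait records")
  refl <- grep("^refl_[0-9]+$", names(records), value = TRUE)
  if (anyNA(match(c("lot_id", "seed_id", MORPH_COLUMNS), names(records))))
    stop("records are missing required trait columns")
  wl <- as.integer(sub("^refl_", "", refl))
  refl <- refl[order(wl)]
  out <- records[c("lot_id", "seed_id", MORPH_COLUMNS, refl)]
  write.csv(format(out, digits = 8, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trait table written by [write_traits_csv()]
#' @param path CSV path.
#' @export
read_traits_csv <- function(path) {
  read.csv(path, check.names = FALSE)
}

#' Export per-genotype phenotypes in GCTA/PLINK dialect
#'
#' Whitespace-delimited, three columns `FID IID value`, no header; missing
#' values written as `NA`.
#'
#' @param lot_means named numeric vector (names = genotype ids) or a two-column
#'   data frame `genotype`, `value`.
#' @param path output path.
#' @export
export_phenotypes <- function(lot_means, path) {
  if (is.data.frame(lot_means)) {
    ids <- as.character(lot_means[[1]]); vals <- lot_means[[2]]
  } else {
    ids <- names(lot_means); vals <- as.numeric(lot_means)
  }
  if (is.null(ids) || any(!nzchar(ids))) stop("genotype ids are required")
  if (anyDuplicated(ids)) stop("duplicate genotype ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  txt <- ifelse(is.finite(vals), format(vals, digits = 8, trim = TRUE,
                                        scientific = FALSE), "NA")
  writeLines(paste(ids, ids, txt), path)
  invisible(path)
}
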