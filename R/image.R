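#' Calibrated grayscale muscle-section image
#'
#' Wraps a 2-D integer raster together with its bit depth and physical pixel
#' size. This is the unit of analysis for the whole pipeline: a
#' single-channel fluorescence image of a laminin-stained cryosection, with
#' bright fiber boundaries and dark fiber interiors.
#'
#' Pixels are stored as an integer matrix with rows = image rows (y) and
#' columns = image columns (x). All geometry in the package uses pixel-corner
#' coordinates: pixel `(row r, col c)` covers `[c-1, c] x [r-1, r]` and has
#' its center at `(c - 0.5, r - 0.5)`.
#'
#' @param pixels integer (or numeric, coerced) matrix of non-negative gray
#'   values, at least 2 x 2.
#' @param bit_depth 8 or 16; all pixels must be `<= 2^bit_depth - 1`.
#' @param pixel_size_um physical edge length of one pixel in micrometers.
#'   Required for calibrated area filtering; if left `NULL` a value of 1 is
#'   used and a warning is emitted.
#' @param name free-text provenance label.
#' @return An object of class `muscle_image` with fields `pixels`,
#'   `bit_depth`, `pixel_size_um`, `name`.
#' @examples
#' img <- muscle_image(matrix(0:255, 16, 16), bit_depth = 8, pixel_size_um = 0.65)
#' dim(img$pixels)
#' @export
muscle_image <- function(pixels, bit_depth = 8L, pixel_size_um = NULL,
                         name = "image") {
  if (is.array(pixels) && length(dim(pixels)) == 3L) {
    stop("multi-channel image: extract a single fluorescence channel first")
  }
  if (!is.matrix(pixels)) stop("'pixels' must be a matrix")
  if (nrow(pixels) < 2L || ncol(pixels) < 2L) {
    stop("image must be at least 2 x 2 pixels")
  }
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  storage.mode(pixels) <- "integer"
  if (anyNA(pixels)) stop("image contains missing pixel values")
  maxval <- 2L^as.integer(bit_depth) - 1L
  if (min(pixels) < 0L || max(pixels) > maxval) {
    stop(sprintf("pixel values must lie in [0, %d] for %d-bit data",
                 maxval, bit_depth))
  }
  if (is.null(pixel_size_um)) {
    warning("pixel_size_um not set; assuming 1 um/pixel - calibrated areas ",
            "will be in pixel units")
    pixel_size_um <- 1
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("pixel_size_um must be a single positive number")
  }
  structure(list(pixels = pixels, bit_depth = as.integer(bit_depth),
                 pixel_size_um = as.numeric(pixel_size_um),
                 name = as.character(name)[1]),
            class = "muscle_image")
}

#' @export
print.muscle_image <- function(x, ...) {
  cat(sprintf("<muscle_image> '%s': %d x %d px, %d-bit, %.4g um/px\n",
              x$name, ncol(x$pixels), nrow(x$pixels), x$bit_depth,
              x$pixel_size_um))
  cat(sprintf("  gray range [%d, %d]\n", min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Read a muscle-section image from TIFF or PNG
#'
#' Reads an 8- or 16-bit single-channel grayscale image. Multi-channel (RGB)
#' input is rejected: the method is defined on one fluorescence channel.
#'
#' @param path path to a `.tif`/`.tiff` or `.png` file.
#' @param pixel_size_um calibration in micrometers per pixel; if `NULL` and
#'   the TIFF carries an x-resolution tag in pixels/cm or pixels/inch, the
#'   calibration is derived from it, otherwise 1 is assumed with a warning.
#' @param name provenance label; defaults to the file name.
#' @return A [muscle_image()].
#' @export
read_muscle_image <- function(path, pixel_size_um = NULL, name = NULL) {
  if (!file.exists(path)) stop("cannot read image: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    raw <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
    bps <- attr(raw, "bits.per.sample")
    bit_depth <- if (!is.null(bps) && bps == 16L) 16L else 8L
    if (is.null(pixel_size_um)) {
      xres <- attr(raw, "x.resolution")
      unit <- attr(raw, "resolution.unit")
      if (!is.null(xres) && is.finite(xres) && xres > 0 && !is.null(unit)) {
        um_per_unit <- switch(as.character(unit), cm = 1e4, inch = 25400,
                              NULL)
        if (!is.null(um_per_unit)) pixel_size_um <- um_per_unit / xres
      }
    }
  } else if (ext == "png") {
    raw <- png::readPNG(path)
    if (length(dim(raw)) == 3L) {
      stop("multi-channel image: extract a single fluorescence channel first")
    }
    # png gives [0,1] doubles; recover the integer code assuming 8 bit
    raw <- round(raw * 255)
    bit_depth <- 8L
  } else {
    stop("unsupported image format: .", ext, " (use TIFF or PNG)")
  }
  if (length(dim(raw)) == 3L) {
    stop("multi-channel image: extract a single fluorescence channel first")
  }
  m <- matrix(as.integer(raw), nrow = dim(raw)[1], ncol = dim(raw)[2])
  muscle_image(m, bit_depth = bit_depth, pixel_size_um = pixel_size_um,
               name = if (is.null(name)) basename(path) else name)
}

#' Write a muscle-section image (or label raster) to TIFF
#'
#' @param image a [muscle_image()], or an integer matrix (written 16-bit).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_muscle_image <- function(image, path) {
  if (inherits(image, "muscle_image")) {
    maxval <- 2^image$bit_depth - 1
    tiff::writeTIFF(image$pixels / maxval, path,
                    bits.per.sample = image$bit_depth)
  } else {
    if (!is.matrix(image)) stop("expected a muscle_image or a matrix")
    if (max(image) > 65535L) stop("label values exceed 16-bit TIFF range")
    tiff::writeTIFF(image / 65535, path, bits.per.sample = 16L)
  }
  invisible(path)
}
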