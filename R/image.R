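#' Calibrated RGB image
#'
#' The unit of all downstream measurement: an 8-bit RGB raster together with an
#' isotropic spatial calibration in micrometres per pixel. Pixel values are
#' integers in \[0, 255\] stored in a \code{height x width x 3} array indexed
#' \code{[y + 1, x + 1, channel]} (0-based pixel centres at integer
#' coordinates).
#'
#' @param rgb numeric array \code{h x w x 3} with values in \[0, 255\].
#' @param um_per_px isotropic calibration, micrometres per pixel (> 0).
#' @return An object of class \code{cathi_image}.
#' @examples
#' img <- calibrated_image(array(255, dim = c(4, 4, 3)), um_per_px = 0.5)
#' dim(img$rgb)
#' @export
calibrated_image <- function(rgb, um_per_px) {
  if (!is.array(rgb) || length(dim(rgb)) != 3L || dim(rgb)[3] != 3L) {
    stop("`rgb` must be an h x w x 3 array", call. = FALSE)
  }
  if (any(rgb < 0 | rgb > 255)) stop("`rgb` values must lie in [0, 255]", call. = FALSE)
  assert_scalar_pos(um_per_px, "um_per_px")
  structure(list(rgb = round(rgb), um_per_px = um_per_px),
            class = "cathi_image")
}

#' @export
print.cathi_image <- function(x, ...) {
  d <- dim(x$rgb)
  cat(sprintf("<cathi_image> %d x %d px, %.4g um/px (%.4g x %.4g um)\n",
              d[2], d[1], x$um_per_px, d[2] * x$um_per_px, d[1] * x$um_per_px))
  invisible(x)
}

# Flat gray-scale view used by the segmenters: plain channel mean in [0, 255].
image_gray <- function(image) {
  stopifnot(inherits(image, "cathi_image"))
  (image$rgb[, , 1] + image$rgb[, , 2] + image$rgb[, , 3]) / 3
}

#' Read and write calibrated RGB images (8-bit PNG or TIFF)
#'
#' PNG/TIFF round-trips are lossless for 8-bit RGB data. The calibration is not
#' stored in the raster file and must be supplied on read.
#'
#' @param path file path; format chosen from the extension (.png, .tif/.tiff).
#' @param image a [calibrated_image()].
#' @param um_per_px calibration to attach on read.
#' @return `read_image()` returns a \code{cathi_image}; `write_image()` returns
#'   `path` invisibly.
#' @export
read_image <- function(path, um_per_px) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  if (length(dim(arr)) == 2L) arr <- array(rep(arr, 3), dim = c(dim(arr), 3))
  if (dim(arr)[3] > 3L) arr <- arr[, , 1:3, drop = FALSE]
  calibrated_image(round(arr * 255), um_per_px)
}

#' @rdname read_image
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "cathi_image"))
  ext <- tolower(tools::file_ext(path))
  arr <- image$rgb / 255
  switch(ext,
    png = png::writePNG(arr, path),
    tif = ,
    tiff = tiff::writeTIFF(arr, path, bits.per.sample = 8L,
                           compression = "none"),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  invisible(path)
}

#' Read and write integer label masks (16-bit TIFF or 8-bit PNG)
#'
#' Label masks are integer matrices with background 0 and one label per object.
#' Round-trips are exact for labels up to 65535 (TIFF) or 255 (PNG).
#'
#' @param mask integer matrix of labels.
#' @param path file path (.tif/.tiff or .png).
#' @return `read_mask()` returns an integer matrix; `write_mask()` returns
#'   `path` invisibly.
#' @export
write_mask <- function(mask, path) {
  if (!is.matrix(mask)) stop("mask must be a matrix", call. = FALSE)
  if (any(mask < 0)) stop("labels must be non-negative", call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (max(mask) > 255) stop("PNG masks support labels up to 255", call. = FALSE)
    png::writePNG(mask / 255, path)
  } else if (ext %in% c("tif", "tiff")) {
    if (max(mask) > 65535) stop("TIFF masks support labels up to 65535", call. = FALSE)
    tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L,
                    compression = "none")
  } else {
    stop("unsupported mask format: .", ext, call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    m <- png::readPNG(path)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    matrix(as.integer(round(m * 255)), nrow = nrow(m))
  } else if (ext %in% c("tif", "tiff")) {
    m <- tiff::readTIFF(path)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    matrix(as.integer(round(m * 65535)), nrow = nrow(m))
  } else {
    stop("unsupported mask format: .", ext, call. = FALSE)
  }
}
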