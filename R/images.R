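#' Write / read 8-bit images as TIFF
#'
#' The package works on demosaiced 8-bit TIFF/PNG exports; these helpers
#' round-trip the integer 0-255 representation without rescaling.
#'
#' @param image Integer matrix or h x w x c array with values 0-255, or a
#'   [render_scene()] result.
#' @param path File path.
#' @return `path` (write, invisibly) or an integer array (read).
#' @export
write_image_tiff <- function(image, path) {
  img <- as_image_array(image)
  if (any(img < 0 | img > 255)) stop("write_image_tiff: values outside 0-255")
  arr <- img / 255
  if (dim(arr)[3] == 1) arr <- arr[, , 1]
  tiff::writeTIFF(arr, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_image_tiff
#' @param channel_names Optional channel labels to attach on read.
#' @export
read_image_tiff <- function(path, channel_names = NULL) {
  arr <- tiff::readTIFF(path, info = TRUE)
  bits <- attr(arr, "bits.per.sample")
  if (!is.null(bits) && bits != 8) {
    stop("read_image_tiff: not an 8-bit image (", bits, " bits per sample)")
  }
  arr <- round(arr * 255)
  if (is.matrix(arr)) arr <- array(arr, dim = c(dim(arr), 1))
  storage.mode(arr) <- "integer"
  as_image_array(arr, channel_names)
}

#' Export / import a reflectance map as 32-bit float TIFF plus flag masks
#'
#' Writes one float TIFF per channel (`<prefix>_<channel>.tif`) and PNG
#' masks for the clipped and low-signal flags
#' (`<prefix>_<channel>_clipped.png`, `..._low_signal.png`). TIFF sample
#' values are constrained to \[0, 1\], so stored values are
#' `reflectance / 2` (super-white pixels up to reflectance 2 survive
#' losslessly); [read_reflectance_maps()] undoes the factor.
#'
#' @param image A reflectance-scale [calibrated_image()].
#' @param prefix Output path prefix.
#' @return Character vector of paths written, invisibly.
#' @export
write_reflectance_maps <- function(image, prefix) {
  stopifnot(inherits(image, "calibrated_image"))
  paths <- character(0)
  for (ch in names(image$channels)) {
    p <- sprintf("%s_%s.tif", prefix, ch)
    v <- image$channels[[ch]] / 2
    if (any(v > 1)) stop("write_reflectance_maps: reflectance above 2 cannot be stored")
    tiff::writeTIFF(v, p, bits.per.sample = 32L)
    paths <- c(paths, p)
    for (fl in c("clipped", "low_signal")) {
      pf <- sprintf("%s_%s_%s.png", prefix, ch, fl)
      png::writePNG(image$flags[[ch]][[fl]] * 1, pf)
      paths <- c(paths, pf)
    }
  }
  invisible(paths)
}

#' @rdname write_reflectance_maps
#' @param channels Channel names to read back.
#' @export
read_reflectance_maps <- function(prefix, channels) {
  chs <- list(); flags <- list()
  for (ch in channels) {
    chs[[ch]] <- tiff::readTIFF(sprintf("%s_%s.tif", prefix, ch)) * 2
    flags[[ch]] <- list(
      clipped = read_mask_png(sprintf("%s_%s_clipped.png", prefix, ch)),
      low_signal = read_mask_png(sprintf("%s_%s_low_signal.png", prefix, ch)))
  }
  calibrated_image(chs, "reflectance", flags)
}

#' Read / write a binary region mask as PNG
#'
#' @param mask Logical matrix.
#' @param path PNG path.
#' @return `path` (write, invisibly) or a logical matrix (read).
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(is.matrix(mask), is.logical(mask))
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m > 0.5
}
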