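#' Calibrated (linear or reflectance-scaled) image
#'
#' Container for per-channel real-valued pixel planes recovered from an
#' 8-bit camera image, together with per-pixel uncertainty and validity
#' flags. `scale` records whether values are relative linear exposures
#' (\[0, 1\]) or reflectance fractions. Reflectance values above 1 can occur
#' when a sample out-reflects the calibration standard (super-white); they
#' are kept and flagged, never clamped.
#'
#' @param channels Named list of numeric matrices (one per channel, equal
#'   dimensions).
#' @param scale `"linear"` or `"reflectance"`.
#' @param flags Named list (per channel) of lists of logical matrices
#'   `clipped`, `low_signal` (same dimensions as the channel).
#' @param uncertainty Named list of numeric matrices (per-pixel SD), or NULL.
#' @return Object of class `calibrated_image`.
#' @export
calibrated_image <- function(channels, scale = c("linear", "reflectance"),
                             flags, uncertainty = NULL) {
  scale <- match.arg(scale)
  d <- dim(channels[[1]])
  for (ch in channels) stopifnot(identical(dim(ch), d))
  for (f in flags) stopifnot(identical(dim(f$clipped), d), identical(dim(f$low_signal), d))
  structure(list(channels = channels, scale = scale, flags = flags,
                 uncertainty = uncertainty),
            class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  nclip <- sum(vapply(x$flags, function(f) sum(f$clipped), numeric(1)))
  cat(sprintf("<calibrated_image:%s> %dx%d, channels: %s, %d clipped px\n",
              x$scale, d[1], d[2], paste(names(x$channels), collapse = ", "), nclip))
  invisible(x)
}

# coerce an input image to an h x w x c integer array with channel names
as_image_array <- function(image, channel_names = NULL) {
  if (inherits(image, "rendered_frame")) return(image$image)
  if (is.matrix(image)) image <- array(image, dim = c(dim(image), 1))
  stopifnot(is.array(image), length(dim(image)) == 3)
  if (is.null(dimnames(image)[[3]])) {
    nm <- channel_names %||% paste0("ch", seq_len(dim(image)[3]))
    dimnames(image) <- list(NULL, NULL, nm)
  }
  image
}

#' Linearise an 8-bit image through per-channel LUTs
#'
#' Replaces every 8-bit pixel value with its relative linear exposure from
#' the channel's linearisation LUT, attaching per-pixel uncertainty (the
#' LUT's bootstrap SD at that level) and two validity masks: pixels above
#' `max_level` are flagged `clipped` (exposure is standardised so the
#' brightest valid response sits exactly at `max_level`, so anything above
#' it is in the saturation zone and radiometrically untrustworthy), and
#' pixels whose linear value falls below the LUT noise floor (default below
#' about 9% of full scale) are flagged `low_signal`.
#'
#' @param image 8-bit image: integer matrix (single channel), h x w x c
#'   array, or a [render_scene()] result. Values outside 0-255 or
#'   non-integer values are an error -- no silent rescaling.
#' @param luts A single [invert_to_lut()] result or a named list, one per
#'   channel.
#' @param max_level Clipping threshold in levels (default 245).
#' @return A linear-scale [calibrated_image()].
#' @export
linearise_image <- function(image, luts, max_level = 245L) {
  img <- as_image_array(image)
  if (any(img < 0 | img > 255) || any(img != round(img))) {
    stop("linearise_image: image is not 8-bit (integer values 0-255); no silent rescale")
  }
  chans <- dimnames(img)[[3]]
  if (inherits(luts, "linear_lut")) {
    luts <- stats::setNames(rep(list(luts), length(chans)), chans)
  }
  if (!all(chans %in% names(luts))) {
    stop("linearise_image: channel count/names do not match the supplied LUTs (",
         paste(chans, collapse = ","), " vs ", paste(names(luts), collapse = ","), ")")
  }
  channels <- list(); flags <- list(); uncert <- list()
  for (ch in chans) {
    lut <- luts[[ch]]
    p <- img[, , ch]
    lin <- matrix(lut$entries[p + 1L], nrow(p), ncol(p))
    sdm <- matrix(lut$uncertainty[p + 1L], nrow(p), ncol(p))
    channels[[ch]] <- lin
    uncert[[ch]] <- sdm
    flags[[ch]] <- list(clipped = p > max_level,
                        low_signal = lin < (lut$noise_floor %||% 0.09) & p <= max_level)
  }
  calibrated_image(channels, "linear", flags, uncert)
}
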