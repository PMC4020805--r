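#' In-frame achromatic reflectance standard
#'
#' Describes one calibration target placed in the photographed frame: a
#' near-perfect white spectrophotometry standard (`white_spectralon`), a
#' barium-sulphate/charcoal grey target reflecting about 33% across the UV
#' band (`grey_33`), or the 'white' patch of a colour checker reflecting
#' about 95% of visible radiation (`checker_white`).
#'
#' @param label One of `"white_spectralon"`, `"grey_33"`, `"checker_white"`
#'   (free-form labels accepted).
#' @param nominal_reflectance Known flat reflectance fraction in (0, 1].
#' @param roi Region of interest: either a logical mask matrix or a list
#'   `list(rows = r1:r2, cols = c1:c2)` (1-based matrix indices).
#' @param valid_band_nm Optional length-2 wavelength interval over which the
#'   target is spectrally flat.
#' @return Object of class `standard_spec`.
#' @export
standard_spec <- function(label, nominal_reflectance, roi, valid_band_nm = NULL) {
  if (!(nominal_reflectance > 0 && nominal_reflectance <= 1)) {
    stop("standard_spec: nominal_reflectance must be in (0, 1]")
  }
  if (is.list(roi)) {
    stopifnot(all(c("rows", "cols") %in% names(roi)))
    if (length(roi$rows) == 0 || length(roi$cols) == 0) stop("standard_spec: empty roi")
  } else if (is.matrix(roi) && is.logical(roi)) {
    if (!any(roi)) stop("standard_spec: empty roi")
  } else stop("standard_spec: roi must be a logical mask or list(rows=, cols=)")
  structure(list(label = label, nominal_reflectance = nominal_reflectance,
                 roi = roi, valid_band_nm = valid_band_nm),
            class = "standard_spec")
}

roi_values <- function(plane, roi) {
  if (is.matrix(roi)) plane[roi] else plane[roi$rows, roi$cols]
}

#' Per-channel exposure scale factors from in-frame standards
#'
#' For each channel independently, estimates the factor converting relative
#' linear exposure to reflectance as `nominal_reflectance / mean(linear ROI
#' values)` over each usable standard, combining multiple standards by
#' inverse-variance weighting (variance of each scale estimate from the ROI
#' sampling variance by the delta method). ROIs containing clipped pixels
#' have those pixels excluded; ROIs that are entirely clipped or entirely
#' below the noise floor are dropped. Calibrating per channel avoids
#' software white balancing: each channel is tied to physics on its own.
#'
#' @param image A linear-scale [calibrated_image()].
#' @param standards List of [standard_spec()].
#' @return Named numeric vector of per-channel scale factors, with a
#'   `details` attribute (data frame of per-standard estimates).
#' @export
calibrate_exposure <- function(image, standards) {
  stopifnot(inherits(image, "calibrated_image"))
  if (image$scale != "linear") stop("calibrate_exposure: image must be on the linear scale")
  if (inherits(standards, "standard_spec")) standards <- list(standards)
  chans <- names(image$channels)
  details <- list()
  scales <- stats::setNames(rep(NA_real_, length(chans)), chans)
  for (ch in chans) {
    plane <- image$channels[[ch]]
    clipped <- image$flags[[ch]]$clipped
    low <- image$flags[[ch]]$low_signal
    est <- c(); var_est <- c(); labs <- c()
    for (st in standards) {
      v <- roi_values(plane, st$roi)
      bad <- roi_values(clipped, st$roi) | roi_values(low, st$roi)
      v <- v[!bad]
      if (length(v) < 1) next
      m <- mean(v)
      if (m <= 0) next
      s <- st$nominal_reflectance / m
      # delta method: var(scale) = nominal^2 * var(mean)/mean^4
      vm <- if (length(v) > 1) stats::var(v) / length(v) else 0
      est <- c(est, s)
      var_est <- c(var_est, st$nominal_reflectance^2 * vm / m^4)
      labs <- c(labs, st$label)
    }
    if (length(est) == 0) {
      stop("calibrate_exposure: no usable (unclipped, above-noise) standard ROI for channel ", ch)
    }
    w <- if (all(var_est == 0)) rep(1, length(est)) else 1 / pmax(var_est, min(var_est[var_est > 0]) * 1e-6)
    scales[ch] <- sum(w * est) / sum(w)
    details[[ch]] <- data.frame(channel = ch, standard = labs, scale = est,
                                variance = var_est)
  }
  attr(scales, "details") <- do.call(rbind, details)
  scales
}

#' Convert a linear image to reflectance scale
#'
#' Multiplies each channel by its exposure scale factor from
#' [calibrate_exposure()]; flags are carried over and per-pixel uncertainty
#' is scaled by the same factor. Values above 1 (super-white) are kept.
#'
#' @param image A linear-scale [calibrated_image()].
#' @param scales Named per-channel factors from [calibrate_exposure()].
#' @return A reflectance-scale [calibrated_image()].
#' @export
to_reflectance <- function(image, scales) {
  stopifnot(inherits(image, "calibrated_image"))
  if (image$scale != "linear") stop("to_reflectance: image is not on the linear scale")
  chans <- names(image$channels)
  if (!all(chans %in% names(scales))) {
    stop("to_reflectance: scales missing for channel(s) ",
         paste(setdiff(chans, names(scales)), collapse = ", "))
  }
  channels <- list(); uncert <- if (is.null(image$uncertainty)) NULL else list()
  for (ch in chans) {
    channels[[ch]] <- image$channels[[ch]] * scales[[ch]]
    if (!is.null(uncert)) uncert[[ch]] <- image$uncertainty[[ch]] * scales[[ch]]
  }
  calibrated_image(channels, "reflectance", image$flags, uncert)
}

#' Saturation / vendor-boost diagnostic on the non-linear image
#'
#' Camera firmware can boost a channel (typically red, for saturated yellow
#' and orange flowers) above its radiometrically faithful value. The
#' diagnostic: in the *non-linear* image, no sample region should out-shine
#' an achromatic standard reflecting more than about 90% of incident
#' radiation. Regions whose mean non-linear value in a channel exceeds the
#' white-class standard's mean are flagged per channel. Clipped regions are
#' reported as clipped and excluded from the boost diagnosis.
#'
#' @param nonlinear_image 8-bit image (matrix, array or [render_scene()]
#'   result).
#' @param standards List of [standard_spec()]; the standard with the highest
#'   nominal reflectance is used as the white reference.
#' @param regions Named list of ROIs (logical mask or `list(rows=, cols=)`)
#'   for the sample regions to screen.
#' @param max_level Clipping threshold (default 245).
#' @return Data frame with one row per region and channel: mean level,
#'   white-standard mean level, and a `status` of `"ok"`, `"boosted"` or
#'   `"clipped"`.
#' @export
saturation_check <- function(nonlinear_image, standards, regions, max_level = 245L) {
  img <- as_image_array(nonlinear_image)
  if (inherits(standards, "standard_spec")) standards <- list(standards)
  nominal <- vapply(standards, `[[`, numeric(1), "nominal_reflectance")
  white <- standards[[which.max(nominal)]]
  chans <- dimnames(img)[[3]]
  rows <- list()
  for (ch in chans) {
    plane <- img[, , ch]
    white_mean <- mean(roi_values(plane, white$roi))
    for (rid in names(regions)) {
      v <- roi_values(plane, regions[[rid]])
      status <- if (mean(v > max_level) > 0.5) "clipped"
                else if (mean(v) > white_mean) "boosted" else "ok"
      rows[[length(rows) + 1]] <- data.frame(
        region = rid, channel = ch, mean_level = mean(v),
        white_level = white_mean, status = status)
    }
  }
  do.call(rbind, rows)
}
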