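#' Predicted linear channel response to a reflecting surface
#'
#' The linear response of a colour channel with spectral sensitivity `S` to
#' an object of reflectance `R` under illuminant `E` is the integral over
#' wavelength of `S(lambda) E(lambda) R(lambda)` (trapezoidal rule). This is
#' the quantity the linearisation pipeline recovers from pixel values.
#'
#' @param sens A [channel_sensitivity()] or a sensitivity [spectrum()]
#'   already sampled on the common grid.
#' @param illuminant Illuminant [spectrum()].
#' @param reflectance Reflectance [spectrum()]. All spectra must share one
#'   grid; mismatched grids are an error (resample explicitly with
#'   [resample_spectrum()]).
#' @return Nonnegative scalar response (arbitrary linear units).
#' @export
predict_response <- function(sens, illuminant, reflectance) {
  if (inherits(sens, "channel_sensitivity")) {
    sens <- evaluate_sensitivity(sens, illuminant$grid)
  }
  stopifnot(inherits(sens, "spectrum"), inherits(illuminant, "spectrum"),
            inherits(reflectance, "spectrum"))
  integrate_spectrum(spectrum_product(sens, illuminant, reflectance))
}

#' Channel response relative to a white reference
#'
#' Ratio of the predicted linear response of a surface to that of a white
#' reference under the same sensitivity and illuminant. For a perfect white
#' reference this is the channel-weighted total reflectance of the surface,
#' the quantity plotted against camera-recovered reflectance when comparing
#' techniques.
#'
#' @inheritParams predict_response
#' @param white_reference Reflectance [spectrum()] of the reference (must
#'   give a nonzero response).
#' @return Scalar in \[0, ~1\] for physical reflectances.
#' @export
predict_relative_reflectance <- function(sens, illuminant, reflectance,
                                         white_reference = NULL) {
  if (is.null(white_reference)) white_reference <- flat_spectrum(1, illuminant$grid)
  denom <- predict_response(sens, illuminant, white_reference)
  if (denom <= 0) stop("predict_relative_reflectance: white reference gives zero response")
  predict_response(sens, illuminant, reflectance) / denom
}

#' Sensor noise specification
#'
#' Zero-mean Gaussian read noise plus a signal-dependent shot-noise-like
#' term, both expressed in 8-bit intensity levels and applied to the linear
#' signal before the transfer nonlinearity: the per-pixel SD is
#' `sqrt(sd_read^2 + shot_coef^2 * signal_levels)` where `signal_levels` is
#' the linear signal on the 0-255 scale.
#'
#' @param sd_read Read-noise SD in intensity levels (default 1).
#' @param shot_coef Shot-noise coefficient (default 0.5); 0 disables.
#' @return Object of class `noise_spec`.
#' @export
noise_spec <- function(sd_read = 1, shot_coef = 0.5) {
  stopifnot(sd_read >= 0, shot_coef >= 0)
  structure(list(sd_read = sd_read, shot_coef = shot_coef), class = "noise_spec")
}

#' No-noise specification
#' @return A [noise_spec()] with both terms zero.
#' @export
no_noise <- function() noise_spec(0, 0)

#' Render a synthetic scene through a camera
#'
#' Forward model used to build ground-truth test imagery: every scene
#' region carries a reflectance spectrum; per channel, the linear response
#' is computed by [predict_response()], scaled by the camera's exposure
#' setting, perturbed by sensor noise, pushed through the channel's
#' transfer function and quantised to 8 bits (clipping at 255).
#'
#' @param scene A [flower_scene()] (any object with `width`, `height`,
#'   `regions` -- each a list with `id`, logical `mask`, `spectrum` -- and a
#'   `background` spectrum).
#' @param camera A [camera_profile()] with exposure standardised
#'   ([standardise_exposure()]).
#' @param noise A [noise_spec()] (default [no_noise()]).
#' @param seed Integer seed for the noise draws (required when noise is on).
#' @return Object of class `rendered_frame`: list with `image` (height x
#'   width x channel integer array, 0-255), `truth` (same shape, the
#'   ground-truth relative reflectance of each pixel per channel),
#'   `channels`, `camera` and `scene`.
#' @export
render_scene <- function(scene, camera, noise = no_noise(), seed = 1) {
  stopifnot(inherits(camera, "camera_profile"), inherits(noise, "noise_spec"))
  if (is.null(camera$exposure)) {
    stop("render_scene: camera exposure is not standardised; call standardise_exposure()")
  }
  illuminant <- camera$illuminant %||% cie_daylight_spd(6500, camera$grid)
  h <- scene$height; w <- scene$width
  chans <- channel_names(camera)
  covered <- matrix(FALSE, h, w)
  regions <- scene$regions
  if (!is.null(scene$background)) {
    regions <- c(regions, list(list(id = ".background", mask = NULL,
                                    spectrum = scene$background)))
  }
  img <- array(0L, dim = c(h, w, length(chans)), dimnames = list(NULL, NULL, chans))
  truth <- array(NA_real_, dim = dim(img), dimnames = dimnames(img))
  white <- flat_spectrum(1, camera$grid)

  # per-region scalar responses per channel
  for (r in scene$regions) covered <- covered | r$mask
  if (is.null(scene$background) && !all(covered)) {
    stop("render_scene: ", sum(!covered), " pixel(s) belong to no region and no background spectrum is set")
  }

  noisy <- noise$sd_read > 0 || noise$shot_coef > 0
  withr::with_seed(seed, {
    for (ci in seq_along(chans)) {
      ch <- chans[ci]
      s <- camera$sensitivities[[ch]]
      tf <- camera$transfers[[ch]]
      scale <- camera$exposure$scale_per_channel[[ch]]
      q_white <- predict_response(s, illuminant, white)
      plane <- matrix(0, h, w)
      tplane <- matrix(NA_real_, h, w)
      for (r in regions) {
        sp <- r$spectrum
        if (is.null(sp)) stop("render_scene: region '", r$id, "' has no spectrum")
        if (!same_grid(sp$grid, camera$grid)) {
          stop("render_scene: region '", r$id, "' spectrum is not on the camera grid")
        }
        q <- predict_response(s, illuminant, sp)
        mask <- if (is.null(r$mask)) !covered else r$mask
        plane[mask] <- scale * q
        tplane[mask] <- q / q_white
      }
      if (noisy) {
        lv <- plane * 255
        sd_lv <- sqrt(noise$sd_read^2 + noise$shot_coef^2 * pmax(lv, 0))
        lv <- lv + stats::rnorm(length(lv), 0, sd_lv)
        plane <- pmax(lv, 0) / 255
      }
      qn <- tf_eval(tf, pmin(pmax(plane, 0), 1))
      px <- round(255 * qn)
      img[, , ci] <- matrix(as.integer(pmin(pmax(px, 0), 255)), h, w)
      truth[, , ci] <- tplane
    }
  })
  structure(list(image = img, truth = truth, channels = chans,
                 camera = camera, scene = scene),
            class = "rendered_frame")
}

#' @export
print.rendered_frame <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<rendered_frame> %dx%d, channels: %s\n", d[1], d[2],
              paste(x$channels, collapse = ", ")))
  invisible(x)
}
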