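#' Exposure setting
#'
#' Per-channel multiplicative exposure scales mapping the predicted linear
#' channel response (integral of sensitivity x illuminant x reflectance) to
#' relative linear sensor exposure in \[0, 1\], plus the calibration level:
#' exposure is standardised so that a perfect white reflector produces a
#' camera response of `max_level` (default 245 of 255), keeping averaged
#' responses clear of clipped pixels.
#'
#' @param scale_per_channel Named positive numeric vector, one scale per
#'   channel.
#' @param max_level Calibration pixel level (default 245).
#' @param bit_depth Bits per channel; only 8 is supported.
#' @return Object of class `exposure_setting`.
#' @export
exposure_setting <- function(scale_per_channel, max_level = 245L, bit_depth = 8L) {
  if (any(scale_per_channel <= 0)) stop("exposure_setting: scales must be positive")
  if (bit_depth != 8L) stop("exposure_setting: only 8-bit images are supported")
  if (max_level <= 0 || max_level >= 2^bit_depth) {
    stop("exposure_setting: max_level must lie strictly inside the bit range")
  }
  structure(list(scale_per_channel = scale_per_channel,
                 max_level = as.integer(max_level), bit_depth = 8L),
            class = "exposure_setting")
}

#' Camera profile
#'
#' Bundles everything the forward model and the linearisation pipeline need
#' to know about a camera: per-channel spectral sensitivities, per-channel
#' transfer functions, the exposure setting, the working wavelength grid
#' and a provenance note.
#'
#' @param name Camera name.
#' @param sensitivities Named list of [channel_sensitivity()], one per channel.
#' @param transfers Named list of [transfer_function()], same channel names.
#' @param exposure An [exposure_setting()] (or `NULL`; see
#'   [standardise_exposure()]).
#' @param grid Working [wavelength_grid()].
#' @param provenance Free-text note on where the coefficients come from.
#' @return Object of class `camera_profile`.
#' @export
camera_profile <- function(name, sensitivities, transfers, exposure = NULL,
                           grid = default_grid(), provenance = "") {
  if (!identical(sort(names(sensitivities)), sort(names(transfers)))) {
    stop("camera_profile: sensitivity and transfer channel names differ")
  }
  for (s in sensitivities) stopifnot(inherits(s, "channel_sensitivity"))
  for (tf in transfers) stopifnot(inherits(tf, "transfer_function"))
  structure(list(name = name, sensitivities = sensitivities,
                 transfers = transfers, exposure = exposure,
                 grid = as_grid(grid), provenance = provenance),
            class = "camera_profile")
}

#' @export
print.camera_profile <- function(x, ...) {
  cat(sprintf("<camera_profile> %s: channels %s%s\n", x$name,
              paste(names(x$sensitivities), collapse = ", "),
              if (is.null(x$exposure)) " (exposure not standardised)" else ""))
  invisible(x)
}

channel_names <- function(camera) names(camera$sensitivities)

#' Standardise exposure so a perfect white maps to the calibration level
#'
#' Computes, independently for each channel, the exposure scale under which
#' a perfect white reflector (reflectance 1 everywhere) yields a camera
#' response of exactly `max_level` intensity levels: the per-channel
#' equivalent of choosing photographic exposure so the brightest in-frame
#' standard sits just below saturation. This is done per channel rather
#' than through a white-balance transform.
#'
#' @param camera A [camera_profile()].
#' @param illuminant Illuminant [spectrum()] on the camera grid (default
#'   D65 via [cie_daylight_spd()]).
#' @param max_level Calibration level (default 245).
#' @return The camera profile with its `exposure` field filled in.
#' @export
standardise_exposure <- function(camera, illuminant = NULL, max_level = 245L) {
  stopifnot(inherits(camera, "camera_profile"))
  if (is.null(illuminant)) illuminant <- cie_daylight_spd(6500, camera$grid)
  if (!same_grid(illuminant$grid, camera$grid)) {
    stop("standardise_exposure: illuminant grid does not match the camera grid")
  }
  white <- flat_spectrum(1, camera$grid)
  scales <- vapply(channel_names(camera), function(ch) {
    q_white <- predict_response(camera$sensitivities[[ch]], illuminant, white)
    if (q_white <= 0) stop("standardise_exposure: channel ", ch, " has zero white response")
    # exposure x_w with f(x_w) = max_level/255, found by bisection
    tf <- camera$transfers[[ch]]
    target <- max_level / 255
    lo <- 0; hi <- 1
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (tf_eval(tf, mid) >= target) hi <- mid else lo <- mid
    }
    ((lo + hi) / 2) / q_white
  }, numeric(1))
  camera$exposure <- exposure_setting(scales, max_level = max_level)
  camera$illuminant <- illuminant
  camera
}

#' Synthetic visible-band camera profile
#'
#' A three-channel (red, green, blue) profile with *synthetic* Gaussian
#' sensitivities and a gamma-like biexponential transfer function shared by
#' the channels. The coefficients are plausible for a consumer DSLR but are
#' not measurements of any physical camera; real profiles should be fitted
#' from characterisation data ([fit_sensitivity()], [fit_transfer()]) or
#' loaded from config ([read_camera_profile()]).
#'
#' @param grid Working grid (default [default_grid()]).
#' @return A [camera_profile()] (exposure not yet standardised).
#' @export
synthetic_visible_profile <- function(grid = default_grid()) {
  sens <- list(
    red   = channel_sensitivity("red",
              data.frame(a = c(1.0, 0.25), b = c(600, 545), c = c(45, 25))),
    green = channel_sensitivity("green", data.frame(a = 1.0, b = 535, c = 50)),
    blue  = channel_sensitivity("blue",  data.frame(a = 1.0, b = 465, c = 40))
  )
  tf <- transfer_function("biexponential",
                          c(a = 0.515604, b = 0.690511, c = -0.507550, d = -8.739707))
  camera_profile("synthetic-visible", sens,
                 transfers = list(red = tf, green = tf, blue = tf),
                 grid = grid,
                 provenance = "synthetic coefficients; not a measured camera")
}

#' Synthetic UV-band camera profile
#'
#' A single-channel profile mimicking the UV-sensitive 'red' channel of a
#' UV-converted DSLR behind a UV-pass filter (sensitivity confined to about
#' 320-395 nm), with a single-exponential transfer function. Synthetic
#' coefficients; see [synthetic_visible_profile()].
#'
#' @param grid Working grid (default [default_grid()]).
#' @return A [camera_profile()] (exposure not yet standardised).
#' @export
synthetic_uv_profile <- function(grid = default_grid()) {
  sens <- list(uv = channel_sensitivity("uv", data.frame(a = 1.0, b = 360, c = 25)))
  tf <- transfer_function("single_exp", c(a = 0.08, b = 2.5))
  camera_profile("synthetic-uv", sens, transfers = list(uv = tf), grid = grid,
                 provenance = "synthetic coefficients; not a measured camera")
}

ci_to_list <- function(ci) {
  if (is.null(ci)) return(NULL)
  lapply(seq_len(nrow(ci)), function(i) as.list(ci[i, ]))
}

ci_from_list <- function(x) {
  if (is.null(x)) return(NULL)
  do.call(rbind, lapply(x, as.data.frame))
}

#' Write / read a camera profile as YAML config
#'
#' Round-trips the full profile: per-channel Gaussian terms with their
#' confidence bounds, transfer-function form/coefficients/bounds, exposure
#' scales, working grid and provenance note.
#'
#' @param camera A [camera_profile()].
#' @param path YAML file path.
#' @return `path` (write, invisibly) or a [camera_profile()] (read).
#' @export
write_camera_profile <- function(camera, path) {
  stopifnot(inherits(camera, "camera_profile"))
  obj <- list(
    name = camera$name,
    provenance = camera$provenance,
    grid = list(start_nm = attr(camera$grid, "start"),
                stop_nm = attr(camera$grid, "stop"),
                step_nm = attr(camera$grid, "step")),
    channels = lapply(channel_names(camera), function(ch) {
      s <- camera$sensitivities[[ch]]
      tf <- camera$transfers[[ch]]
      list(channel_id = ch,
           sensitivity = list(terms = lapply(seq_len(nrow(s$terms)),
                                             function(i) as.list(s$terms[i, ])),
                              ci95 = ci_to_list(s$ci95)),
           transfer = list(form = tf$form,
                           coefficients = as.list(tf$coefficients),
                           ci95 = ci_to_list(tf$ci95)))
    }),
    exposure = if (is.null(camera$exposure)) NULL else {
      list(scale_per_channel = as.list(camera$exposure$scale_per_channel),
           max_level = camera$exposure$max_level,
           bit_depth = camera$exposure$bit_depth)
    }
  )
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_camera_profile
#' @export
read_camera_profile <- function(path) {
  obj <- yaml::read_yaml(path)
  grid <- wavelength_grid(obj$grid$start_nm, obj$grid$stop_nm, obj$grid$step_nm)
  sens <- list(); tfs <- list()
  for (ch in obj$channels) {
    terms <- do.call(rbind, lapply(ch$sensitivity$terms, as.data.frame))
    sens[[ch$channel_id]] <- channel_sensitivity(ch$channel_id, terms,
                                                 ci95 = ci_from_list(ch$sensitivity$ci95))
    tfs[[ch$channel_id]] <- transfer_function(ch$transfer$form,
                                              unlist(ch$transfer$coefficients),
                                              ci95 = ci_from_list(ch$transfer$ci95))
  }
  exposure <- NULL
  if (!is.null(obj$exposure)) {
    exposure <- exposure_setting(unlist(obj$exposure$scale_per_channel),
                                 max_level = obj$exposure$max_level,
                                 bit_depth = obj$exposure$bit_depth)
  }
  camera_profile(obj$name, sens, tfs, exposure = exposure, grid = grid,
                 provenance = obj$provenance %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
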