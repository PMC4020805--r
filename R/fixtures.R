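#' Synthetic scene container
#'
#' A labelled scene for the forward renderer: every region is a logical
#' pixel mask bound to a reflectance spectrum; remaining pixels take the
#' background spectrum. Regions must not overlap.
#'
#' @param width,height Canvas size in pixels.
#' @param regions List of regions, each `list(id, mask, spectrum)` (mask is
#'   a height x width logical matrix).
#' @param background Background reflectance [spectrum()] (or `NULL` if the
#'   regions tile the canvas).
#' @return Object of class `flower_scene`.
#' @export
flower_scene <- function(width, height, regions, background = NULL) {
  seen <- matrix(0L, height, width)
  for (r in regions) {
    stopifnot(is.list(r), !is.null(r$id), is.matrix(r$mask), is.logical(r$mask))
    if (!identical(dim(r$mask), c(as.integer(height), as.integer(width)))) {
      stop("flower_scene: mask of region '", r$id, "' does not match the canvas")
    }
    if (is.null(r$spectrum)) stop("flower_scene: region '", r$id, "' has no spectrum")
    seen <- seen + r$mask
  }
  if (any(seen > 1)) stop("flower_scene: regions overlap")
  structure(list(width = as.integer(width), height = as.integer(height),
                 regions = regions, background = background),
            class = "flower_scene")
}

#' Rectangular and disk masks
#'
#' Helpers for building scene regions. Coordinates are 1-based matrix
#' indices (row, col).
#'
#' @param height,width Canvas size.
#' @param rows,cols Index ranges for the rectangle.
#' @return Logical height x width matrix.
#' @export
mask_rect <- function(height, width, rows, cols) {
  m <- matrix(FALSE, height, width)
  m[rows, cols] <- TRUE
  m
}

#' @rdname mask_rect
#' @param centre Length-2 (row, col) disk centre.
#' @param radius Disk radius in pixels.
#' @export
mask_disk <- function(height, width, centre, radius) {
  rr <- matrix(seq_len(height), height, width)
  cc <- matrix(seq_len(width), height, width, byrow = TRUE)
  (rr - centre[1])^2 + (cc - centre[2])^2 <= radius^2
}

#' Parametric petal reflectance spectra
#'
#' Idealised floral reflectance classes built from a baseline, a logistic
#' long-pass edge and Gaussian bands -- enough structure to imitate a
#' (human-perceived) yellow petal with either UV-reflective or UV-absorbing
#' patterning, plus flat achromatic classes. These imitate the broad shape
#' of measured petal spectra; they are synthetic, not measurements.
#'
#' @param class Spectrum class: `"yellow"` (long-pass edge near 520 nm, low
#'   UV), `"yellow_uv"` (yellow plus a UV reflectance band near 360 nm),
#'   `"uv_absorbing"` (yellow with UV pulled to ~2%), `"white"` (flat 0.85),
#'   `"grey"` (flat 0.33), `"background"` (flat 0.08).
#' @param grid Wavelength grid.
#' @param uv_reflectance Peak UV-band reflectance for `"yellow_uv"`
#'   (default 0.30).
#' @return A reflectance [spectrum()].
#' @export
petal_spectrum <- function(class = c("yellow", "yellow_uv", "uv_absorbing",
                                     "white", "grey", "background"),
                           grid = default_grid(), uv_reflectance = 0.30) {
  class <- match.arg(class)
  wl <- as.numeric(as_grid(grid))
  yellow <- 0.05 + 0.75 / (1 + exp(-(wl - 520) / 15))
  v <- switch(class,
    yellow = yellow,
    yellow_uv = yellow + uv_reflectance * exp(-((wl - 360) / 30)^2),
    uv_absorbing = pmax(yellow - 0.04 * exp(-((wl - 360) / 40)^2), 0.02),
    white = rep(0.85, length(wl)),
    grey = rep(0.33, length(wl)),
    background = rep(0.08, length(wl)))
  spectrum(as_grid(grid), pmin(v, 1), type = "reflectance")
}

#' Grey-ramp characterisation series
#'
#' Simulates the exposure-ramp exercise used to characterise a camera's
#' transfer function: `n_steps` relative exposures log-spaced over
#' \[0.02, 1\], each observed as the mean (and SD) of a patch of noisy
#' pixels. With noise off the mean pixel values lie exactly on the transfer
#' curve, so [fit_transfer()] on the output recovers the generating
#' coefficients.
#'
#' @param tf A [transfer_function()].
#' @param n_steps Number of exposure steps (>= 6, default 12).
#' @param noise A [noise_spec()] (default [no_noise()]).
#' @param seed Seed for the pixel noise.
#' @param n_pixels Pixels averaged per step (default 400).
#' @return Data frame `rel_exposure, mean_pixel, sd_pixel` (pixel values
#'   normalised to \[0, 1\]).
#' @export
make_grey_series <- function(tf, n_steps = 12, noise = no_noise(), seed = 1,
                             n_pixels = 400) {
  stopifnot(inherits(tf, "transfer_function"))
  if (n_steps < 6) stop("make_grey_series: need at least 6 steps")
  x <- 10^seq(log10(0.02), 0, length.out = n_steps)
  noisy <- noise$sd_read > 0 || noise$shot_coef > 0
  if (!noisy) {
    q <- tf_eval(tf, x)
    return(data.frame(rel_exposure = x, mean_pixel = q, sd_pixel = 0))
  }
  withr::with_seed(seed, {
    mp <- numeric(n_steps); sp <- numeric(n_steps)
    for (i in seq_len(n_steps)) {
      lv <- x[i] * 255
      sd_lv <- sqrt(noise$sd_read^2 + noise$shot_coef^2 * lv)
      xi <- pmin(pmax((lv + stats::rnorm(n_pixels, 0, sd_lv)) / 255, 0), 1)
      qi <- tf_eval(tf, xi)
      mp[i] <- mean(qi); sp[i] <- stats::sd(qi)
    }
    data.frame(rel_exposure = x, mean_pixel = mp, sd_pixel = sp)
  })
}

#' Neutral-swatch calibration frame
#'
#' Renders a vertical strip of spectrally flat neutral swatches next to a
#' perfect white reference: the classic test chart for evaluating a
#' linearisation function end to end. The default reflectances are the six
#' colour-checker neutral patches, bottom to top: 3.10%, 9.11%, 19.5%,
#' 37.2%, 60.9% and 94.8%.
#'
#' @param reflectances Swatch reflectance fractions in (0, 1].
#' @param camera A [camera_profile()] (exposure is standardised in place if
#'   missing).
#' @param noise A [noise_spec()] (default [no_noise()]).
#' @param seed Seed for the noise draws.
#' @param swatch_px Swatch edge in pixels (default 30).
#' @return List with `frame` (a [render_scene()] result), `standards`
#'   (a [standard_spec()] list containing the white reference), `swatch_rois`
#'   (named list of ROI specs, `swatch_1` = bottom), and `reflectances`.
#' @export
make_swatch_frame <- function(reflectances = c(0.0310, 0.0911, 0.195, 0.372, 0.609, 0.948),
                              camera = synthetic_visible_profile(),
                              noise = no_noise(), seed = 1, swatch_px = 30) {
  if (any(reflectances <= 0 | reflectances > 1)) {
    stop("make_swatch_frame: reflectances must be in (0, 1]")
  }
  n <- length(reflectances)
  h <- n * swatch_px
  w <- 2 * swatch_px
  if (is.null(camera$exposure)) camera <- standardise_exposure(camera)
  regions <- list()
  rois <- list()
  for (i in seq_len(n)) {
    # swatch 1 at the bottom of the strip
    rows <- (h - i * swatch_px + 1):(h - (i - 1) * swatch_px)
    regions[[i]] <- list(id = sprintf("swatch_%d", i),
                         mask = mask_rect(h, w, rows, 1:swatch_px),
                         spectrum = flat_spectrum(reflectances[i], camera$grid))
    rois[[sprintf("swatch_%d", i)]] <- list(rows = rows, cols = 1:swatch_px)
  }
  white_roi <- list(rows = 1:h, cols = (swatch_px + 1):w)
  regions[[n + 1]] <- list(id = "white_standard",
                           mask = mask_rect(h, w, white_roi$rows, white_roi$cols),
                           spectrum = flat_spectrum(1, camera$grid))
  scene <- flower_scene(w, h, regions, background = NULL)
  frame <- render_scene(scene, camera, noise = noise, seed = seed)
  list(frame = frame,
       standards = list(standard_spec("white_spectralon", 1.0, white_roi)),
       swatch_rois = rois, reflectances = reflectances, camera = camera)
}

#' Synthetic flower scene with in-frame standards
#'
#' Builds a parametric flower on a 512 x 512 canvas (a disk "corolla" large
#' enough to admit a 4 x 3 grid of 40 px cells) together with the three
#' in-frame calibration targets -- white spectralon, 33% grey, 95% checker
#' white -- and a dim background. Templates:
#' \describe{
#'   \item{plain}{single-spectrum petals (UV-reflective yellow).}
#'   \item{bullseye}{UV-absorbing centre inside a UV-reflective corolla:
#'     the classic UV floral guide, invisible to humans.}
#'   \item{gradient}{petal reflectance stepped radially over five bands.}
#' }
#' The seed jitters the flower centre and radius by a few pixels so
#' replicate scenes differ in layout but not in spectra; the same seed
#' reproduces the scene exactly.
#'
#' @param template `"bullseye"`, `"gradient"` or `"plain"`.
#' @param params Optional list: `uv_mark_reflectance` (default 0.30),
#'   `radius` (default 170), `mark_radius` (default 70).
#' @param seed Integer seed.
#' @param grid Wavelength grid.
#' @return List with `scene` (a [flower_scene()]), `standards`
#'   ([standard_spec()] list), `region_spectra` (ground-truth spectra by
#'   region id) and `flower_bbox` (0-based top-left of a 4x3/40 px grid
#'   inside the corolla).
#' @export
make_flower_scene <- function(template = c("bullseye", "gradient", "plain"),
                              params = list(), seed = 1, grid = default_grid()) {
  template <- match.arg(template)
  p <- utils::modifyList(list(uv_mark_reflectance = 0.30, radius = 170, mark_radius = 70),
                         params)
  h <- 512L; w <- 512L
  jit <- withr::with_seed(seed, stats::runif(3, -1, 1))
  centre <- c(276 + round(6 * jit[1]), 256 + round(6 * jit[2]))
  radius <- p$radius + round(4 * jit[3])

  petal_sp <- petal_spectrum("yellow_uv", grid, uv_reflectance = p$uv_mark_reflectance)
  disk <- mask_disk(h, w, centre, radius)
  regions <- list()
  if (template == "plain") {
    regions <- list(list(id = "petal", mask = disk, spectrum = petal_sp))
  } else if (template == "bullseye") {
    mark <- mask_disk(h, w, centre, p$mark_radius) & disk
    regions <- list(
      list(id = "petal", mask = disk & !mark, spectrum = petal_sp),
      list(id = "uv_mark", mask = mark, spectrum = petal_spectrum("uv_absorbing", grid)))
  } else { # gradient: five radial reflectance steps
    rr <- matrix(seq_len(h), h, w); cc <- matrix(seq_len(w), h, w, byrow = TRUE)
    dist <- sqrt((rr - centre[1])^2 + (cc - centre[2])^2)
    edges <- seq(0, radius, length.out = 6)
    fac <- seq(1.0, 0.55, length.out = 5)
    wl <- as.numeric(grid)
    for (i in 1:5) {
      m <- disk & dist > edges[i] & dist <= edges[i + 1]
      regions[[i]] <- list(id = sprintf("band_%d", i), mask = m,
                           spectrum = spectrum(grid, petal_sp$values * fac[i]))
    }
  }

  std_defs <- list(
    list(label = "white_spectralon", nominal = 1.00, rows = 11:50, cols = 11:50,
         sp = flat_spectrum(1, grid)),
    list(label = "grey_33", nominal = 0.33, rows = 11:50, cols = 463:502,
         sp = petal_spectrum("grey", grid)),
    list(label = "checker_white", nominal = 0.95, rows = 463:502, cols = 11:50,
         sp = flat_spectrum(0.95, grid)))
  standards <- list()
  for (sdef in std_defs) {
    regions[[length(regions) + 1]] <- list(id = sdef$label,
                                           mask = mask_rect(h, w, sdef$rows, sdef$cols),
                                           spectrum = sdef$sp)
    standards[[length(standards) + 1]] <- standard_spec(sdef$label, sdef$nominal,
                                                        list(rows = sdef$rows, cols = sdef$cols))
  }
  scene <- flower_scene(w, h, regions, background = petal_spectrum("background", grid))
  region_spectra <- stats::setNames(lapply(regions, `[[`, "spectrum"),
                                    vapply(regions, `[[`, character(1), "id"))
  # 0-based top-left corner of a 4x3 grid of 40 px cells centred in the corolla
  bbox <- list(row = centre[1] - 80L, col = centre[2] - 60L)
  list(scene = scene, standards = standards, region_spectra = region_spectra,
       flower_bbox = bbox, centre = centre, radius = radius, template = template)
}
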