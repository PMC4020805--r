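#' Sampled spectrum
#'
#' A spectrum is a nonnegative function of wavelength sampled on a
#' [wavelength_grid()]: a reflectance spectrum (fraction of incident
#' radiation, normally in \[0, 1\]), the relative spectral power of an
#' illuminant (arbitrary scale), or a channel sensitivity curve.
#'
#' Reflectance values above 1.05 are tolerated -- field measurements can
#' exceed the white standard -- but the spectrum is flagged `super_white`
#' and a warning is emitted.
#'
#' @param grid A [wavelength_grid()] (or a uniformly spaced numeric vector).
#' @param values Numeric vector, one value per grid point, all finite and
#'   nonnegative.
#' @param type One of `"reflectance"`, `"illuminant"`, `"sensitivity"`.
#'
#' @return An object of class `spectrum`: list with elements `grid`,
#'   `values`, `type` and logical `super_white`.
#' @examples
#' s <- spectrum(wavelength_grid(400, 700), rep(0.33, 301))
#' integrate_spectrum(s)
#' @export
spectrum <- function(grid, values, type = c("reflectance", "illuminant", "sensitivity")) {
  type <- match.arg(type)
  grid <- as_grid(grid)
  values <- as.numeric(values)
  if (length(values) != length(grid)) {
    stop(sprintf("spectrum: %d values for %d grid points", length(values), length(grid)))
  }
  if (any(!is.finite(values))) stop("spectrum: values must be finite")
  if (any(values < 0)) stop("spectrum: values must be nonnegative")
  super_white <- FALSE
  if (type == "reflectance" && any(values > 1.05)) {
    super_white <- TRUE
    warning(sprintf("reflectance exceeds 1.05 at %d grid point(s); flagged super_white",
                    sum(values > 1.05)))
  }
  structure(list(grid = grid, values = values, type = type,
                 super_white = super_white),
            class = "spectrum")
}

#' Spectrally flat spectrum
#'
#' @param value Constant value at every wavelength.
#' @param grid Wavelength grid (default [default_grid()]).
#' @param type Spectrum type, as in [spectrum()].
#' @return A [spectrum()].
#' @export
flat_spectrum <- function(value, grid = default_grid(), type = "reflectance") {
  spectrum(grid, rep(value, length(grid)), type = type)
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum:%s> %g-%g nm (%d pts), values in [%.4g, %.4g]%s\n",
              x$type, x$grid[1], x$grid[length(x$grid)], length(x$grid),
              min(x$values), max(x$values),
              if (isTRUE(x$super_white)) " [super_white]" else ""))
  invisible(x)
}

#' Resample a spectrum onto a target grid
#'
#' Linear interpolation inside the source support. Target wavelengths
#' outside the source support get the value 0 and a truncation warning is
#' emitted (no extrapolation); grids that do not overlap at all are an
#' error.
#'
#' @param sp A [spectrum()].
#' @param target A [wavelength_grid()].
#' @return A [spectrum()] on `target`.
#' @export
resample_spectrum <- function(sp, target) {
  stopifnot(inherits(sp, "spectrum"))
  target <- as_grid(target)
  src <- as.numeric(sp$grid)
  lo <- src[1]; hi <- src[length(src)]
  tw <- as.numeric(target)
  if (max(tw) < lo || min(tw) > hi) {
    stop("resample_spectrum: no overlap between source and target grids")
  }
  outside <- tw < lo - 1e-9 | tw > hi + 1e-9
  vals <- stats::approx(src, sp$values, xout = tw, rule = 1)$y
  vals[is.na(vals)] <- 0
  vals[outside] <- 0
  if (any(outside)) {
    warning(sprintf("resample_spectrum: %d target point(s) outside source support set to 0 (truncated)",
                    sum(outside)))
  }
  out <- suppressWarnings(spectrum(target, vals, type = sp$type))
  out$super_white <- sp$super_white
  out
}

#' Trapezoidal integral of a spectrum
#'
#' @param sp A [spectrum()] with at least two grid points.
#' @return Scalar integral over the grid, in value-times-nanometre units.
#' @export
integrate_spectrum <- function(sp) {
  stopifnot(inherits(sp, "spectrum"))
  if (length(sp$grid) < 2) stop("integrate_spectrum: need at least 2 grid points")
  pracma::trapz(as.numeric(sp$grid), sp$values)
}

# pointwise product of spectra on the same grid (used in the forward model)
spectrum_product <- function(...) {
  sps <- list(...)
  g <- sps[[1]]$grid
  for (s in sps[-1]) {
    if (!same_grid(g, s$grid)) stop("grid mismatch: spectra are on different wavelength grids")
  }
  v <- Reduce(`*`, lapply(sps, `[[`, "values"))
  suppressWarnings(spectrum(g, v, type = "sensitivity"))
}

#' Read a spectrum from CSV
#'
#' Expects the two-column layout `wavelength_nm,value` with a header.
#' Reflectance files holding percentages (0-100) are converted with
#' `percent = TRUE`.
#'
#' @param path CSV file path.
#' @param percent If `TRUE`, divide values by 100.
#' @param type Spectrum type, as in [spectrum()].
#' @return A [spectrum()].
#' @export
read_spectrum_csv <- function(path, percent = FALSE, type = "reflectance") {
  df <- utils::read.csv(path)
  if (!all(c("wavelength_nm", "value") %in% names(df))) {
    stop("read_spectrum_csv: expected columns wavelength_nm,value")
  }
  v <- df$value
  if (percent) v <- v / 100
  spectrum(as_grid(df$wavelength_nm), v, type = type)
}

#' Write a spectrum to CSV
#'
#' @param sp A [spectrum()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(sp, path) {
  stopifnot(inherits(sp, "spectrum"))
  utils::write.csv(data.frame(wavelength_nm = as.numeric(sp$grid), value = sp$values),
                   path, row.names = FALSE)
  invisible(path)
}
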