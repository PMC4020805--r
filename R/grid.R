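#' Regular wavelength grid
#'
#' A uniformly spaced wavelength axis in nanometres on which spectra,
#' sensitivities and illuminants are sampled. The grid points are
#' `start_nm + k * step_nm` and must land exactly on `stop_nm`.
#'
#' @param start_nm First wavelength (nm).
#' @param stop_nm Last wavelength (nm); must exceed `start_nm`.
#' @param step_nm Positive spacing (nm). Default 1 nm.
#'
#' @return An object of class `wavelength_grid`: a numeric vector of
#'   wavelengths with `start`, `stop` and `step` attributes.
#' @examples
#' g <- wavelength_grid(400, 700)
#' length(g)
#' @export
wavelength_grid <- function(start_nm, stop_nm, step_nm = 1) {
  stopifnot(is.numeric(start_nm), is.numeric(stop_nm), is.numeric(step_nm))
  if (!(start_nm < stop_nm)) {
    stop("wavelength_grid: start_nm must be strictly less than stop_nm")
  }
  if (step_nm <= 0) stop("wavelength_grid: step_nm must be positive")
  n_steps <- (stop_nm - start_nm) / step_nm
  if (abs(n_steps - round(n_steps)) > 1e-8) {
    stop("wavelength_grid: step_nm must divide the interval exactly")
  }
  wl <- start_nm + seq.int(0L, round(n_steps)) * step_nm
  structure(wl,
            start = start_nm, stop = stop_nm, step = step_nm,
            class = c("wavelength_grid", "numeric"))
}

#' Default working grid
#'
#' 300-710 nm at 1 nm, spanning the UV band recorded through a Baader-U
#' type filter (roughly 320-395 nm) and the visible band (400-710 nm),
#' with margin on the short side.
#'
#' @return A [wavelength_grid()].
#' @export
default_grid <- function() wavelength_grid(300, 710, 1)

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("<wavelength_grid> %g-%g nm, step %g nm (%d points)\n",
              attr(x, "start"), attr(x, "stop"), attr(x, "step"), length(x)))
  invisible(x)
}

# grids equal up to float noise
same_grid <- function(a, b) {
  length(a) == length(b) && max(abs(as.numeric(a) - as.numeric(b))) < 1e-9
}

as_grid <- function(x) {
  if (inherits(x, "wavelength_grid")) return(x)
  x <- as.numeric(x)
  if (length(x) < 2) stop("a wavelength grid needs at least 2 points")
  d <- diff(x)
  if (any(d <= 0)) stop("wavelengths must be strictly increasing")
  if (max(d) - min(d) > 1e-6) {
    stop("wavelengths are not uniformly spaced; build spectra on a regular grid")
  }
  wavelength_grid(x[1], x[length(x)], d[1])
}
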