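# CIE daylight-series components: mean vector S0 and the first two
# characteristic vectors S1, S2, tabulated 300-830 nm at 10 nm.
# Standard published constants (Wyszecki & Stiles tabulation).
cie_daylight_components <- function() {
  list(
    wl = seq(300, 830, 10),
    S0 = c(0.04, 6.00, 29.60, 55.30, 57.30, 61.80, 61.50, 68.80, 63.40, 65.80,
           94.80, 104.80, 105.90, 96.80, 113.90, 125.60, 125.50, 121.30, 121.30, 113.50,
           113.10, 110.80, 106.50, 108.80, 105.30, 104.40, 100.00, 96.00, 95.10, 89.10,
           90.50, 90.30, 88.40, 84.00, 85.10, 81.90, 82.60, 84.90, 81.30, 71.90,
           74.30, 76.40, 63.30, 71.70, 77.00, 65.20, 47.70, 68.60, 65.00, 66.00,
           61.00, 53.30, 58.90, 61.90),
    S1 = c(0.02, 4.50, 22.40, 42.00, 40.60, 41.60, 38.00, 42.40, 38.50, 35.00,
           43.40, 46.30, 43.90, 37.10, 36.70, 35.90, 32.60, 27.90, 24.30, 20.10,
           16.20, 13.20, 8.60, 6.10, 4.20, 1.90, 0.00, -1.60, -3.50, -3.50,
           -5.80, -7.20, -8.60, -9.50, -10.90, -10.70, -12.00, -14.00, -13.60, -12.00,
           -13.30, -12.90, -10.60, -11.60, -12.20, -10.20, -7.80, -11.20, -10.40, -10.60,
           -9.70, -8.30, -9.30, -9.80),
    S2 = c(0.00, 2.00, 4.00, 8.50, 7.80, 6.70, 5.30, 6.10, 3.00, 1.20,
           -1.10, -0.50, -0.70, -1.20, -2.60, -2.90, -2.80, -2.60, -2.60, -1.80,
           -1.50, -1.30, -1.20, -1.00, -0.50, -0.30, 0.00, 0.20, 0.50, 2.10,
           3.20, 4.10, 4.70, 5.10, 6.70, 7.30, 8.60, 9.80, 10.20, 8.30,
           9.60, 8.50, 7.00, 7.60, 8.00, 6.70, 5.20, 7.40, 6.80, 7.00,
           6.40, 5.50, 6.10, 6.50)
  )
}

#' CIE daylight-series illuminant
#'
#' Synthesises the relative spectral power distribution of a CIE daylight
#' phase from its correlated colour temperature: the daylight chromaticity
#' (x_D, y_D) is computed from the CCT, the weights M1, M2 of the two
#' characteristic vectors follow from the chromaticity, and the SPD is
#' `S0 + M1 S1 + M2 S2`, normalised to 100 at 560 nm. At 6500 K this is the
#' D65 reference illuminant.
#'
#' Nominal CCTs of the canonical daylight phases historically refer to the
#' older value of the radiation constant c2; `cct_correction = TRUE`
#' (default) applies the conventional rescaling by 1.4388/1.4380 (6500 K
#' becomes 6504 K), which reproduces the published D65 tabulation.
#'
#' @param cct_kelvin Correlated colour temperature in K, in \[4000, 25000\].
#' @param grid Output [wavelength_grid()] (default [default_grid()]).
#'   Wavelengths outside the tabulated 300-830 nm range get 0.
#' @param cct_correction Apply the c2 rescaling of the nominal CCT.
#' @return A [spectrum()] of type `"illuminant"`, relative power with the
#'   convention value 100 at 560 nm.
#' @examples
#' d65 <- cie_daylight_spd(6500, wavelength_grid(300, 710, 5))
#' @export
cie_daylight_spd <- function(cct_kelvin, grid = default_grid(), cct_correction = TRUE) {
  if (!is.numeric(cct_kelvin) || length(cct_kelvin) != 1 ||
      cct_kelvin < 4000 || cct_kelvin > 25000) {
    stop("cie_daylight_spd: cct_kelvin must be a single value in [4000, 25000]")
  }
  grid <- as_grid(grid)
  T <- if (cct_correction) cct_kelvin * 1.4388 / 1.4380 else cct_kelvin
  xD <- if (T <= 7000) {
    -4.6070e9 / T^3 + 2.9678e6 / T^2 + 0.09911e3 / T + 0.244063
  } else {
    -2.0064e9 / T^3 + 1.9018e6 / T^2 + 0.24748e3 / T + 0.237040
  }
  yD <- -3.000 * xD^2 + 2.870 * xD - 0.275
  M  <- 0.0241 + 0.2562 * xD - 0.7341 * yD
  M1 <- (-1.3515 - 1.7703 * xD + 5.9114 * yD) / M
  M2 <- (0.0300 - 31.4424 * xD + 30.0717 * yD) / M
  comp <- cie_daylight_components()
  spd10 <- comp$S0 + M1 * comp$S1 + M2 * comp$S2
  # the components are defined so S(560) = 100 (S1 = S2 = 0 there); renormalise
  # anyway to guard against interpolation of the convention point
  spd10 <- spd10 / spd10[comp$wl == 560] * 100
  tw <- as.numeric(grid)
  vals <- stats::approx(comp$wl, spd10, xout = tw, rule = 1)$y
  vals[is.na(vals)] <- 0
  vals[vals < 0] <- 0
  spectrum(grid, vals, type = "illuminant")
}
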