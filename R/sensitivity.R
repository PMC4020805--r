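#' Gaussian-sum channel spectral sensitivity
#'
#' The relative spectral sensitivity of a camera colour channel is modelled
#' as a sum of one or two Gaussian terms,
#' `S(lambda) = sum_k a_k * exp(-((lambda - b_k)/c_k)^2)`,
#' with nonnegative amplitudes `a_k`, peak wavelengths `b_k` (nm, within
#' 250-800 nm) and positive widths `c_k` (nm).
#'
#' @param channel_id Channel label, one of `"red"`, `"green"`, `"blue"`, `"uv"`
#'   (free-form labels are accepted but these are conventional).
#' @param terms Data frame (or coercible) with columns `a`, `b`, `c`; one or
#'   two rows.
#' @param ci95 Optional data frame of 95% confidence bounds with columns
#'   `coef`, `lower`, `upper` (one row per fitted coefficient).
#' @return Object of class `channel_sensitivity`.
#' @examples
#' s <- channel_sensitivity("green", data.frame(a = 1, b = 530, c = 40))
#' @export
channel_sensitivity <- function(channel_id, terms, ci95 = NULL) {
  terms <- as.data.frame(terms)
  if (!all(c("a", "b", "c") %in% names(terms))) {
    stop("channel_sensitivity: terms must have columns a, b, c")
  }
  if (!nrow(terms) %in% 1:2) stop("channel_sensitivity: 1 or 2 Gaussian terms required")
  if (any(terms$a < 0)) stop("channel_sensitivity: amplitudes must be nonnegative")
  if (any(terms$c <= 0)) stop("channel_sensitivity: widths must be positive")
  if (any(terms$b < 250 | terms$b > 800)) {
    stop("channel_sensitivity: centres must lie within 250-800 nm")
  }
  structure(list(channel_id = as.character(channel_id),
                 terms = terms[, c("a", "b", "c")], ci95 = ci95),
            class = "channel_sensitivity")
}

#' @export
print.channel_sensitivity <- function(x, ...) {
  cat(sprintf("<channel_sensitivity:%s> %d term(s)\n", x$channel_id, nrow(x$terms)))
  print(round(x$terms, 4))
  invisible(x)
}

#' Evaluate a channel sensitivity on a wavelength grid
#'
#' @param sens A [channel_sensitivity()].
#' @param grid A [wavelength_grid()].
#' @return A [spectrum()] of type `"sensitivity"`.
#' @export
evaluate_sensitivity <- function(sens, grid) {
  stopifnot(inherits(sens, "channel_sensitivity"))
  grid <- as_grid(grid)
  wl <- as.numeric(grid)
  v <- rep(0, length(wl))
  for (k in seq_len(nrow(sens$terms))) {
    v <- v + sens$terms$a[k] * exp(-((wl - sens$terms$b[k]) / sens$terms$c[k])^2)
  }
  spectrum(grid, v, type = "sensitivity")
}

#' Area-normalise a sensitivity curve
#'
#' Divides a sampled sensitivity by the total area under the curve so the
#' normalised curve integrates to 1. This is the convention used when
#' plotting camera channels next to photoreceptor sensitivities.
#'
#' @param sens_spectrum A [spectrum()] with positive area.
#' @return A [spectrum()] integrating to 1.
#' @export
normalise_sensitivity <- function(sens_spectrum) {
  area <- integrate_spectrum(sens_spectrum)
  if (area <= 0) stop("normalise_sensitivity: zero-area input")
  spectrum(sens_spectrum$grid, sens_spectrum$values / area, type = sens_spectrum$type)
}

# Wald 95% CI table from an nls-type fit
wald_ci95 <- function(fit) {
  est <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) rep(NA_real_, length(est)))
  df <- tryCatch(stats::df.residual(fit), error = function(e) Inf)
  if (!is.finite(df) || df < 1) df <- Inf
  tq <- stats::qt(0.975, df)
  data.frame(coef = names(est), estimate = unname(est),
             lower = unname(est - tq * se), upper = unname(est + tq * se))
}

ci_excludes_zero <- function(ci) {
  all(is.finite(ci$lower) & is.finite(ci$upper) & (ci$lower > 0 | ci$upper < 0))
}

# parsimony gate for the nested simple/complex model pair: the complex
# model must be supported by very strong evidence, delta-BIC <= -10 (the
# Kass-Raftery scale), guarding against borderline noise features whose
# coefficients are formally significant. A (near-)perfect simple fit keeps
# the simple model: the models are then indistinguishable and the extra
# terms are unidentifiable.
nested_model_improves <- function(fit_simple, fit_complex, dbic = -10) {
  rss1 <- stats::deviance(fit_simple)
  rss2 <- stats::deviance(fit_complex)
  scale2 <- max(1, sum(stats::fitted(fit_simple)^2))
  if (rss1 <= 1e-16 * scale2) return(FALSE)
  if (rss2 <= 1e-16 * scale2) return(TRUE)
  delta <- tryCatch(stats::BIC(fit_complex) - stats::BIC(fit_simple),
                    error = function(e) NA_real_)
  isTRUE(delta <= dbic)
}

#' Fit a Gaussian-sum sensitivity model to measured samples
#'
#' Fits both the one-term and the two-term Gaussian model by nonlinear
#' least squares and retains the two-term model only when every one of its
#' six coefficients is individually significant (its 95% Wald confidence
#' interval excludes zero) *and* the richer model is supported by very
#' strong evidence (BIC lower by at least 10, the Kass-Raftery scale). The
#' second condition guards against two failure modes of the significance
#' rule alone: an unidentifiable split of one peak into two overlapping
#' "significant" halves, and a borderline noise bump fitted as a tiny yet
#' formally significant band. Otherwise the one-term model is returned.
#' Term widths are bounded below by the sampling step, since a band
#' narrower than the sample spacing is unresolvable.
#'
#' Initial values: peak centre at the wavelength of the largest sample,
#' amplitude at the largest sample, width from the full-width-half-maximum
#' estimate; the second term is seeded at the largest residual peak of the
#' one-term fit.
#'
#' @param wavelength_nm Numeric vector of sampled wavelengths (>= 8 points).
#' @param sensitivity Measured relative sensitivity at those wavelengths.
#' @param channel_id Channel label stored on the result.
#' @return A [channel_sensitivity()] carrying `ci95` for the selected model.
#' @export
fit_sensitivity <- function(wavelength_nm, sensitivity, channel_id = "unknown") {
  wl <- as.numeric(wavelength_nm); y <- as.numeric(sensitivity)
  if (length(wl) != length(y)) stop("fit_sensitivity: length mismatch")
  if (length(wl) < 8) stop("fit_sensitivity: need at least 8 sample points")
  dat <- data.frame(wl = wl, y = y)

  fwhm_width <- function(wl, y) {
    imax <- which.max(y)
    half <- y[imax] / 2
    above <- which(y >= half)
    span <- diff(range(wl[above]))
    if (span <= 0) span <- diff(range(wl)) / 4
    span / (2 * sqrt(log(2)))   # FWHM = 2*sqrt(ln 2)*c for exp(-((x-b)/c)^2)
  }

  imax <- which.max(y)
  # a band narrower than the sampling step is unidentifiable: bound widths
  # below by the median spacing so noise spikes cannot pose as terms
  min_width <- max(1, stats::median(diff(sort(wl))))
  start1 <- list(a1 = y[imax], b1 = wl[imax], c1 = max(fwhm_width(wl, y), min_width))
  fit1 <- tryCatch(
    minpack.lm::nlsLM(y ~ a1 * exp(-((wl - b1) / c1)^2), data = dat, start = start1,
                      lower = c(0, 250, min_width), upper = c(Inf, 800, 500),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)

  fit2 <- NULL
  if (!is.null(fit1)) {
    res <- y - stats::predict(fit1)
    jres <- which.max(abs(res))
    p1 <- stats::coef(fit1)
    start2 <- list(a1 = p1[["a1"]], b1 = p1[["b1"]], c1 = p1[["c1"]],
                   a2 = max(abs(res[jres]), 0.05 * y[imax]),
                   b2 = wl[jres], c2 = max(p1[["c1"]] / 2, min_width))
    fit2 <- tryCatch(
      minpack.lm::nlsLM(y ~ a1 * exp(-((wl - b1) / c1)^2) + a2 * exp(-((wl - b2) / c2)^2),
                        data = dat, start = start2,
                        lower = c(0, 250, min_width, 0, 250, min_width),
                        upper = c(Inf, 800, 500, Inf, 800, 500),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
  }
  if (is.null(fit1) && is.null(fit2)) {
    stop("fit_sensitivity: neither the 1-term nor the 2-term model converged (",
         length(wl), " samples, peak at ", wl[imax], " nm)")
  }

  use2 <- !is.null(fit2) && ci_excludes_zero(wald_ci95(fit2)) &&
    (is.null(fit1) || nested_model_improves(fit1, fit2))
  fit <- if (use2) fit2 else fit1
  p <- stats::coef(fit)
  terms <- if (use2) {
    data.frame(a = c(p[["a1"]], p[["a2"]]), b = c(p[["b1"]], p[["b2"]]),
               c = c(p[["c1"]], p[["c2"]]))
  } else {
    data.frame(a = p[["a1"]], b = p[["b1"]], c = p[["c1"]])
  }
  # keep terms ordered by centre for reproducible comparisons
  terms <- terms[order(terms$b), , drop = FALSE]
  rownames(terms) <- NULL
  out <- channel_sensitivity(channel_id, terms, ci95 = wald_ci95(fit))
  out$vcov <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  out
}
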