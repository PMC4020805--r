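#' Camera transfer function
#'
#' The nonlinearity linking relative linear exposure `x` (normalised to
#' \[0, 1\]) to the normalised pixel value `q` (also \[0, 1\]): the "gain"
#' of the camera response model, which folds in vendor gamma correction.
#' Two parametric families are supported, plus the identity:
#' \describe{
#'   \item{single_exp}{`q(x) = a * exp(b x)`, coefficients `(a, b)`.}
#'   \item{biexponential}{`q(x) = a * exp(b x) + c * exp(d x)`,
#'     coefficients `(a, b, c, d)`.}
#'   \item{identity}{`q(x) = x`, no coefficients: a technical camera whose
#'     gain is constant, so the response is already linear.}
#' }
#' The stored direction is exposure to pixel; linearisation uses the
#' numerical inverse (see [invert_to_lut()]). A valid transfer function is
#' strictly increasing on \[0, 1\] with `q(0) >= 0` and `q(1) <= 1.05`;
#' fitted curves that drift slightly past the range bounds under
#' characterisation noise are tolerated with a warning and flagged
#' (`out_of_bounds`), since the LUT clamps those levels anyway, while
#' grossly out-of-range curves (`q(0) < -0.05` or `q(1) > 1.5`) and
#' non-monotonic curves are rejected.
#'
#' @param form `"single_exp"` or `"biexponential"`.
#' @param coefficients Named or positional numeric vector: `(a, b)` or
#'   `(a, b, c, d)`.
#' @param ci95 Optional data frame of 95% confidence bounds (`coef`,
#'   `estimate`, `lower`, `upper`).
#' @return Object of class `transfer_function`.
#' @examples
#' tf <- transfer_function("single_exp", c(a = 0.08, b = 2.5))
#' tf_eval(tf, c(0, 0.5, 1))
#' @export
transfer_function <- function(form = c("single_exp", "biexponential", "identity"),
                              coefficients = numeric(0), ci95 = NULL) {
  form <- match.arg(form)
  p <- as.numeric(coefficients)
  n_expected <- switch(form, single_exp = 2L, biexponential = 4L, identity = 0L)
  if (length(p) != n_expected) {
    stop(sprintf("transfer_function: %s needs %d coefficients, got %d",
                 form, n_expected, length(p)))
  }
  names(p) <- letters[seq_along(p)]
  tf <- structure(list(form = form, coefficients = p, ci95 = ci95,
                       out_of_bounds = FALSE),
                  class = "transfer_function")
  x <- seq(0, 1, length.out = 513)
  q <- tf_eval(tf, x)
  if (any(diff(q) <= 0)) stop("transfer_function: not strictly increasing on [0, 1]")
  if (q[1] < -0.05) stop("transfer_function: q(0) is grossly negative")
  if (q[length(q)] > 1.5) stop("transfer_function: q(1) exceeds 1.5; curve is not normalised")
  if (q[1] < 0 || q[length(q)] > 1.05) {
    tf$out_of_bounds <- TRUE
    warning(sprintf("transfer_function: range [%.3f, %.3f] drifts past [0, 1.05]; flagged",
                    q[1], q[length(q)]))
  }
  tf
}

#' Evaluate a transfer function (exposure to normalised pixel value)
#'
#' @param tf A [transfer_function()].
#' @param x Relative exposure value(s).
#' @return Normalised pixel value(s).
#' @export
tf_eval <- function(tf, x) {
  tf_eval_coef(tf$form, unname(tf$coefficients), x)
}

tf_eval_coef <- function(form, p, x) {
  switch(form,
         identity = x,
         single_exp = p[1] * exp(p[2] * x),
         biexponential = p[1] * exp(p[2] * x) + p[3] * exp(p[4] * x))
}

#' @export
print.transfer_function <- function(x, ...) {
  cat(sprintf("<transfer_function:%s> %s\n", x$form,
              paste(sprintf("%s=%.6g", names(x$coefficients), x$coefficients), collapse = ", ")))
  invisible(x)
}

#' Fit a camera transfer function to a characterisation series
#'
#' Least-squares fit of the single-exponential and/or biexponential model
#' to paired (relative exposure, mean pixel value) observations from a
#' grey-ramp characterisation exercise. When the series carries a
#' `sd_pixel` column (the pixel SD within each characterisation patch), the
#' fit is weighted by the inverse squared SD, so exposure steps measured
#' more precisely count more. With `form = "auto"`, the biexponential model
#' is retained only when all four of its coefficients are individually
#' significant (95% Wald CI excluding zero), the richer model is supported
#' by very strong evidence (BIC lower by at least 10), and the fitted curve
#' is strictly increasing on \[0, 1\]; otherwise the single-exponential fit
#' is returned. Fits that are non-monotonic on \[0, 1\] are rejected.
#'
#' @param series Data frame with columns `rel_exposure` (in \[0, 1\]) and
#'   `mean_pixel` (either normalised \[0, 1\] or 8-bit 0-255; 8-bit input is
#'   detected and divided by 255), optionally `sd_pixel` on the same scale.
#'   At least 6 steps spanning \[0.05, 0.95\] are required.
#' @param form `"auto"` (default), `"single_exp"` or `"biexponential"`.
#' @return A [transfer_function()] with Wald `ci95` and the coefficient
#'   covariance matrix (`$vcov`) for uncertainty propagation.
#' @export
fit_transfer <- function(series, form = c("auto", "single_exp", "biexponential")) {
  form <- match.arg(form)
  series <- as.data.frame(series)
  if (!all(c("rel_exposure", "mean_pixel") %in% names(series))) {
    stop("fit_transfer: series needs columns rel_exposure, mean_pixel")
  }
  x <- as.numeric(series$rel_exposure)
  q <- as.numeric(series$mean_pixel)
  eight_bit <- max(q) > 1.5
  if (eight_bit) q <- q / 255
  if (length(x) < 6) stop("fit_transfer: need at least 6 exposure steps")
  if (min(x) > 0.05 || max(x) < 0.95) {
    stop("fit_transfer: series must span at least [0.05, 0.95] relative exposure")
  }
  w <- NULL
  if ("sd_pixel" %in% names(series)) {
    sdp <- as.numeric(series$sd_pixel)
    if (eight_bit) sdp <- sdp / 255
    if (all(is.finite(sdp)) && all(sdp > 0)) w <- 1 / sdp^2
  }
  dat <- data.frame(x = x, q = q)

  monotone_ok <- function(fit, f) {
    p <- stats::coef(fit)
    v <- tf_eval_coef(f, unname(p), seq(0, 1, length.out = 513))
    all(diff(v) > 0) && v[1] >= -0.05 && v[length(v)] <= 1.5
  }

  nls_fit <- function(formula, start, maxiter) {
    args <- list(formula, data = dat, start = start,
                 control = minpack.lm::nls.lm.control(maxiter = maxiter))
    if (!is.null(w)) args$weights <- w
    tryCatch(do.call(minpack.lm::nlsLM, args), error = function(e) NULL)
  }

  fit_single <- function() {
    pos <- q > 0
    sl <- stats::lm(log(q[pos]) ~ x[pos])
    start <- list(a = exp(unname(stats::coef(sl)[1])), b = unname(stats::coef(sl)[2]))
    nls_fit(q ~ a * exp(b * x), start, 500)
  }
  fit_biexp <- function(f1) {
    starts <- list()
    if (!is.null(f1)) {
      p1 <- stats::coef(f1)
      r0 <- q[which.min(x)] - tf_eval_coef("single_exp", unname(p1), min(x))
      starts[[1]] <- list(a = p1[["a"]], b = p1[["b"]],
                          c = if (abs(r0) > 1e-6) r0 else -p1[["a"]] / 2, d = -6)
    }
    starts[[length(starts) + 1]] <- list(a = 0.5, b = 0.7, c = -0.45, d = -7)
    starts[[length(starts) + 1]] <- list(a = 0.2, b = 1.5, c = -0.2, d = -12)
    starts[[length(starts) + 1]] <- list(a = 0.05, b = 3, c = 0.05, d = 1)
    for (s in starts) {
      f <- nls_fit(q ~ a * exp(b * x) + c * exp(d * x), s, 1000)
      if (!is.null(f) && monotone_ok(f, "biexponential")) return(f)
    }
    NULL
  }

  make_tf <- function(fit, f) {
    if (!monotone_ok(fit, f)) {
      stop("fit_transfer: best ", f, " fit is non-monotonic on [0, 1]; rejected")
    }
    out <- suppressWarnings(transfer_function(f, stats::coef(fit), ci95 = wald_ci95(fit)))
    if (out$out_of_bounds) {
      message("fit_transfer: fitted ", f, " drifts slightly past the [0, 1.05] range; ",
              "affected levels will be clamped in the LUT")
    }
    out$vcov <- tryCatch(stats::vcov(fit), error = function(e) NULL)
    out
  }

  if (form == "single_exp") {
    f1 <- fit_single()
    if (is.null(f1)) stop("fit_transfer: single-exponential fit did not converge")
    return(make_tf(f1, "single_exp"))
  }
  if (form == "biexponential") {
    f2 <- fit_biexp(fit_single())
    if (is.null(f2)) stop("fit_transfer: biexponential fit did not converge or was non-monotonic")
    return(make_tf(f2, "biexponential"))
  }
  # auto
  f1 <- fit_single()
  f2 <- fit_biexp(f1)
  if (!is.null(f2) && ci_excludes_zero(wald_ci95(f2)) &&
      (is.null(f1) || nested_model_improves(f1, f2))) {
    return(make_tf(f2, "biexponential"))
  }
  if (!is.null(f1)) return(make_tf(f1, "single_exp"))
  if (!is.null(f2)) return(make_tf(f2, "biexponential"))
  stop("fit_transfer: neither transfer model converged (", length(x), " steps)")
}

#' Invert a transfer function into an 8-bit linearisation LUT
#'
#' For every 8-bit pixel level `p`, the relative linear exposure
#' `f^{-1}(p/255)` is found by bisection (tolerance 1e-9, exposure clamped
#' to \[0, 1\]). Levels below `f(0)*255` (the black offset of a pure
#' exponential) or above `f(1)*255` are clamped and flagged. Per-entry
#' uncertainty is propagated by a seeded parametric bootstrap of the fitted
#' coefficients: draws come from the multivariate normal with the fit's
#' coefficient covariance when the transfer function carries one
#' (correlations between coefficients matter for the inverse), falling back
#' to independent normals matched to the Wald intervals otherwise; each
#' draw is inverted and the per-level SD across draws is stored, both
#' absolute and relative to the entry. For a gamma-like (concave) transfer
#' the steep toe makes the *absolute* SD small at low levels while the
#' *relative* SD is largest there -- the practically relevant statement that
#' recovered values below the noise floor are unreliable.
#'
#' @param tf A [transfer_function()].
#' @param n_boot Bootstrap draws for uncertainty (default 1000; 0 disables).
#' @param seed Seed for the bootstrap draws.
#' @param noise_floor Relative linear exposure below which recovered values
#'   are considered noise-dominated (default 0.09, i.e. about 9% of full
#'   scale).
#' @return Object of class `linear_lut`: list with `entries` (256
#'   non-decreasing exposures), `uncertainty` (256 SDs, NA when `n_boot = 0`
#'   or no CIs), `rel_uncertainty` (SD divided by the entry; NA at zero
#'   entries), `flag` (256 strings: `"ok"`, `"clamped_low"`,
#'   `"clamped_high"`, `"low_signal"`), `noise_floor_level` (largest pixel
#'   level whose exposure is below the floor) and the source `tf`.
#' @export
invert_to_lut <- function(tf, n_boot = 1000, seed = 1, noise_floor = 0.09) {
  stopifnot(inherits(tf, "transfer_function"))
  targets <- (0:255) / 255

  invert_all <- function(p) {
    f <- function(x) tf_eval_coef(tf$form, p, x)
    f0 <- f(0); f1 <- f(1)
    lo <- rep(0, 256); hi <- rep(1, 256)
    below <- targets <= f0; above <- targets >= f1
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      fm <- f(mid)
      take_hi <- fm >= targets
      hi[take_hi] <- mid[take_hi]
      lo[!take_hi] <- mid[!take_hi]
    }
    x <- (lo + hi) / 2
    x[below] <- 0; x[above] <- 1
    list(x = x, below = below, above = above)
  }

  base <- invert_all(unname(tf$coefficients))
  entries <- base$x
  flag <- rep("ok", 256)
  flag[base$below] <- "clamped_low"
  flag[base$above] <- "clamped_high"
  low <- entries < noise_floor & flag == "ok"
  flag[low] <- "low_signal"

  uncertainty <- rep(NA_real_, 256)
  if (n_boot > 0 && (!is.null(tf$vcov) || !is.null(tf$ci95))) {
    est <- if (!is.null(tf$ci95)) tf$ci95$estimate else unname(tf$coefficients)
    k <- length(est)
    draws <- withr::with_seed(seed, {
      z <- matrix(stats::rnorm(n_boot * k), n_boot, k)
      if (!is.null(tf$vcov)) {
        L <- tryCatch(chol(tf$vcov), error = function(e) NULL)
        if (!is.null(L)) {
          z %*% L + matrix(est, n_boot, k, byrow = TRUE)
        } else {
          sds <- sqrt(pmax(diag(tf$vcov), 0))
          sweep(z, 2, sds, `*`) + matrix(est, n_boot, k, byrow = TRUE)
        }
      } else {
        sds <- (tf$ci95$upper - tf$ci95$lower) / (2 * stats::qnorm(0.975))
        sds[!is.finite(sds)] <- 0
        sweep(z, 2, sds, `*`) + matrix(est, n_boot, k, byrow = TRUE)
      }
    })
    acc <- matrix(NA_real_, nrow = n_boot, ncol = 256)
    for (i in seq_len(n_boot)) {
      p <- draws[i, ]
      # skip coefficient draws giving a non-increasing curve
      v <- tf_eval_coef(tf$form, p, seq(0, 1, length.out = 65))
      if (any(diff(v) <= 0)) next
      acc[i, ] <- invert_all(p)$x
    }
    uncertainty <- apply(acc, 2, stats::sd, na.rm = TRUE)
  }

  nf_levels <- which(entries < noise_floor)
  structure(list(entries = entries, uncertainty = uncertainty,
                 rel_uncertainty = ifelse(entries > 0, uncertainty / entries, NA_real_),
                 flag = flag,
                 noise_floor_level = if (length(nf_levels)) max(nf_levels) - 1L else -1L,
                 noise_floor = noise_floor, tf = tf),
            class = "linear_lut")
}

#' @export
print.linear_lut <- function(x, ...) {
  cat(sprintf("<linear_lut> 256 entries, noise floor %.0f%% (level <= %d), %d clamped\n",
              100 * x$noise_floor, x$noise_floor_level,
              sum(x$flag %in% c("clamped_low", "clamped_high"))))
  invisible(x)
}

#' Write / read a linearisation LUT as CSV
#'
#' Columns `level,linear_value,sd,flag`.
#'
#' @param lut A [invert_to_lut()] result.
#' @param path CSV path.
#' @return `path` (write) or a `linear_lut` without the source transfer
#'   function (read), invisibly for the writer.
#' @export
write_lut_csv <- function(lut, path) {
  stopifnot(inherits(lut, "linear_lut"))
  utils::write.csv(data.frame(level = 0:255, linear_value = lut$entries,
                              sd = lut$uncertainty, flag = lut$flag),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lut_csv
#' @export
read_lut_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("level", "linear_value", "sd", "flag") %in% names(df)) || nrow(df) != 256) {
    stop("read_lut_csv: expected 256 rows of level,linear_value,sd,flag")
  }
  df <- df[order(df$level), ]
  entries <- df$linear_value
  nf_levels <- which(df$flag == "low_signal" | df$flag == "clamped_low")
  structure(list(entries = entries, uncertainty = df$sd,
                 rel_uncertainty = ifelse(entries > 0, df$sd / entries, NA_real_),
                 flag = as.character(df$flag),
                 noise_floor_level = if (length(nf_levels)) max(df$level[nf_levels]) else -1L,
                 noise_floor = NA_real_, tf = NULL),
            class = "linear_lut")
}

#' Write / read a characterisation series as CSV
#'
#' Columns `rel_exposure,mean_pixel,sd_pixel`.
#'
#' @param series Data frame as produced by [make_grey_series()].
#' @param path CSV path.
#' @return `path` (write) or the data frame (read).
#' @export
write_series_csv <- function(series, path) {
  stopifnot(all(c("rel_exposure", "mean_pixel") %in% names(series)))
  if (!"sd_pixel" %in% names(series)) series$sd_pixel <- NA_real_
  utils::write.csv(series[, c("rel_exposure", "mean_pixel", "sd_pixel")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("rel_exposure", "mean_pixel") %in% names(df))) {
    stop("read_series_csv: expected columns rel_exposure,mean_pixel[,sd_pixel]")
  }
  df
}
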