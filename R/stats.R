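sample_values <- function(x, mode = "means") {
  if (is.numeric(x)) return(as.numeric(x))
  if (inherits(x, "region_sample")) x <- list(x)
  if (mode == "means") {
    vapply(x, `[[`, numeric(1), "mean")
  } else {
    unlist(lapply(x, `[[`, "values"), use.names = FALSE)
  }
}

#' Compare camera-recovered and spectrophotometer-predicted reflectance
#'
#' Two-sided Wilcoxon rank-sum test between camera-derived region values
#' and predicted channel responses. The exact null distribution is used
#' when the combined sample size is at most 20 and there are no ties; the
#' normal approximation with continuity correction is used otherwise. A
#' rank-based test is used because recovered reflectance distributions over
#' floral regions are frequently non-normal (see [normality_check()]).
#'
#' @param camera List of [region_sample()] (or a numeric vector) of
#'   camera-recovered values.
#' @param predicted Numeric vector of predicted relative reflectances (from
#'   [predict_relative_reflectance()] applied to spectrophotometer
#'   readings).
#' @param mode `"means"` (default): one value per region; `"pixels"`: pool
#'   all retained pixel values.
#' @return List of class `method_comparison`: `statistic` (W), `p_value`,
#'   `exact`, group means/SDs/sizes, `direction` (sign of camera minus
#'   predicted mean) and `note` (tie handling warnings).
#' @export
compare_methods <- function(camera, predicted, mode = c("means", "pixels")) {
  mode <- match.arg(mode)
  x <- sample_values(camera, mode)
  y <- as.numeric(predicted)
  if (length(x) < 3 || length(y) < 3) {
    stop("compare_methods: need at least 3 values on each side")
  }
  note <- NULL
  ties <- anyDuplicated(c(x, y)) > 0
  degenerate <- length(unique(c(x, y))) == 1
  if (degenerate) {
    note <- "all values tied on both sides; maximal p reported"
    warning("compare_methods: ", note)
    return(structure(list(statistic = length(x) * length(y) / 2, p_value = 1,
                          exact = FALSE,
                          mean_camera = mean(x), sd_camera = stats::sd(x), n_camera = length(x),
                          mean_predicted = mean(y), sd_predicted = stats::sd(y), n_predicted = length(y),
                          direction = 0, note = note),
                     class = "method_comparison"))
  }
  exact <- (length(x) + length(y)) <= 20 && !ties
  if (ties) note <- "ties present; normal approximation with continuity correction"
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided",
                                            exact = exact, correct = TRUE))
  structure(list(statistic = unname(wt$statistic), p_value = wt$p.value, exact = exact,
                 mean_camera = mean(x), sd_camera = stats::sd(x), n_camera = length(x),
                 mean_predicted = mean(y), sd_predicted = stats::sd(y), n_predicted = length(y),
                 direction = sign(mean(x) - mean(y)), note = note),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum (%s): W = %g, p = %.4g\n",
              if (x$exact) "exact" else "normal approx.", x$statistic, x$p_value))
  cat(sprintf("  camera    : mean %.4g, sd %.4g, n %d\n", x$mean_camera, x$sd_camera, x$n_camera))
  cat(sprintf("  predicted : mean %.4g, sd %.4g, n %d\n", x$mean_predicted, x$sd_predicted, x$n_predicted))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Per-channel method comparison with Holm correction
#'
#' Runs [compare_methods()] independently for each channel and reports the
#' per-channel (uncorrected) p-values alongside a Holm-adjusted column
#' (the adjustment is an extension beyond the per-channel presentation).
#'
#' @param camera_by_channel Named list: channel -> list of [region_sample()]
#'   or numeric vector.
#' @param predicted_by_channel Named list: channel -> numeric vector.
#' @param mode Passed to [compare_methods()].
#' @return Data frame with one row per channel.
#' @export
compare_methods_by_channel <- function(camera_by_channel, predicted_by_channel,
                                       mode = "means") {
  chans <- names(camera_by_channel)
  res <- lapply(chans, function(ch) {
    compare_methods(camera_by_channel[[ch]], predicted_by_channel[[ch]], mode = mode)
  })
  df <- data.frame(channel = chans,
                   W = vapply(res, `[[`, numeric(1), "statistic"),
                   p_value = vapply(res, `[[`, numeric(1), "p_value"),
                   mean_camera = vapply(res, `[[`, numeric(1), "mean_camera"),
                   mean_predicted = vapply(res, `[[`, numeric(1), "mean_predicted"),
                   direction = vapply(res, `[[`, numeric(1), "direction"))
  df$p_holm <- stats::p.adjust(df$p_value, method = "holm")
  df
}

#' Shapiro-Wilk normality check of a region sample
#'
#' Used to decide whether rank-based comparison is warranted: recovered
#' reflectance values over patterned floral regions are often significantly
#' non-normal.
#'
#' @param sample A [region_sample()] or numeric vector with 3 to 5000
#'   values.
#' @return List with `W`, `p_value`, `n`.
#' @export
normality_check <- function(sample) {
  x <- if (inherits(sample, "region_sample")) sample$values else as.numeric(sample)
  if (length(x) < 3 || length(x) > 5000) {
    stop("normality_check: sample size must be in [3, 5000], got ", length(x))
  }
  if (length(unique(x)) == 1) stop("normality_check: constant sample")
  sw <- stats::shapiro.test(x)
  list(W = unname(sw$statistic), p_value = sw$p.value, n = length(x))
}

#' Per-channel spatio-chromatic variability summary
#'
#' Summarises how strongly recovered reflectance varies across sampled
#' regions in each spectral band: per-channel mean of region means, pooled
#' SD (combining within-region variance and between-region spread of all
#' retained pixel values), histogram bins of the pooled values, and a
#' ranking of channels by dispersion (1 = most variable; ties share a
#' rank).
#'
#' @param samples_by_channel Named list: channel -> list of
#'   [region_sample()] (at least 2 regions per channel).
#' @param bins Number of histogram bins (default 12).
#' @return List of class `variability_summary` with a `table` data frame
#'   (`channel, n_regions, mean_of_means, pooled_sd, dispersion_rank`) and
#'   `histograms` (named list of `hist`-style breaks/counts).
#' @export
variability_summary <- function(samples_by_channel, bins = 12) {
  chans <- names(samples_by_channel)
  for (ch in chans) {
    s <- samples_by_channel[[ch]]
    if (inherits(s, "region_sample") || length(s) < 2) {
      stop("variability_summary: need at least 2 regions per channel (channel ", ch, ")")
    }
  }
  pooled <- lapply(samples_by_channel, function(s) {
    unlist(lapply(s, `[[`, "values"), use.names = FALSE)
  })
  tab <- data.frame(
    channel = chans,
    n_regions = vapply(samples_by_channel, length, integer(1)),
    mean_of_means = vapply(samples_by_channel, function(s) {
      mean(vapply(s, `[[`, numeric(1), "mean"))
    }, numeric(1)),
    pooled_sd = vapply(pooled, stats::sd, numeric(1))
  )
  # rank 1 = widest dispersion; exact ties share the same (min) rank
  tab$dispersion_rank <- rank(-tab$pooled_sd, ties.method = "min")
  hists <- lapply(pooled, function(v) {
    h <- graphics::hist(v, breaks = bins, plot = FALSE)
    list(breaks = h$breaks, counts = h$counts)
  })
  structure(list(table = tab, histograms = hists), class = "variability_summary")
}

#' @export
print.variability_summary <- function(x, ...) {
  print(x$table, row.names = FALSE)
  invisible(x)
}
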