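#' Region sample summary
#'
#' Summary of calibrated pixel values over one sampled region of one
#' channel. Clipped and low-signal pixels are excluded from the values and
#' counted in `flags_excluded`, so
#' `pixel_count == length(values) + flags_excluded`.
#'
#' @param region_id Region label.
#' @param channel Channel label.
#' @param values Retained per-pixel values (kept for rank tests).
#' @param flags_excluded Number of pixels removed by validity flags.
#' @return Object of class `region_sample` with fields `region_id`,
#'   `channel`, `pixel_count`, `mean`, `sd`, `values`, `flags_excluded`.
#' @export
region_sample <- function(region_id, channel, values, flags_excluded = 0L) {
  values <- as.numeric(values)
  structure(list(region_id = region_id, channel = channel,
                 pixel_count = length(values) + as.integer(flags_excluded),
                 mean = if (length(values)) mean(values) else NA_real_,
                 sd = if (length(values) > 1) stats::sd(values) else 0,
                 values = values,
                 flags_excluded = as.integer(flags_excluded)),
            class = "region_sample")
}

#' @export
print.region_sample <- function(x, ...) {
  cat(sprintf("<region_sample> %s/%s: n=%d mean=%.4g sd=%.4g (%d excluded)\n",
              x$region_id, x$channel, x$pixel_count, x$mean, x$sd, x$flags_excluded))
  invisible(x)
}

#' Tabulate region samples
#'
#' @param samples List of [region_sample()] objects.
#' @return Data frame with columns `region_id,channel,n,mean,sd,excluded`.
#' @export
sample_report <- function(samples) {
  if (inherits(samples, "region_sample")) samples <- list(samples)
  do.call(rbind, lapply(samples, function(s) {
    data.frame(region_id = s$region_id, channel = s$channel, n = s$pixel_count,
               mean = s$mean, sd = s$sd, excluded = s$flags_excluded)
  }))
}

sample_square <- function(image, row0, col0, half_size, channels, id) {
  # row0/col0 are 0-based centre coordinates (origin top-left)
  d <- dim(image$channels[[1]])
  r <- (row0 - half_size):(row0 + half_size)
  cc <- (col0 - half_size):(col0 + half_size)
  if (min(r) < 0 || min(cc) < 0 || max(r) >= d[1] || max(cc) >= d[2]) {
    stop(sprintf("sample square around centre (%d, %d) falls outside the %dx%d image",
                 row0, col0, d[1], d[2]))
  }
  lapply(channels, function(ch) {
    v <- image$channels[[ch]][r + 1, cc + 1]
    bad <- image$flags[[ch]]$clipped[r + 1, cc + 1] |
      image$flags[[ch]]$low_signal[r + 1, cc + 1]
    region_sample(id, ch, v[!bad], flags_excluded = sum(bad))
  })
}

#' Point sampling of square pixel areas
#'
#' Samples square areas of `(2*half_size + 1)^2` pixels -- by default
#' 15 x 15 = 225 pixels, the footprint comparable to a spectrophotometer
#' probe -- around given centres of a calibrated image. Pixel coordinates
#' are 0-based, row-major with the origin at the top-left; squares include
#' both borders. Clipped and low-signal pixels are excluded and counted.
#'
#' @param image A [calibrated_image()].
#' @param centres Data frame (or 2-column matrix) of 0-based `row`, `col`
#'   centre coordinates.
#' @param half_size Half-width in pixels (default 7, giving 15 x 15).
#' @param channels Channels to sample (default all).
#' @return List of [region_sample()], one per centre per channel.
#' @export
point_sample <- function(image, centres, half_size = 7L, channels = NULL) {
  stopifnot(inherits(image, "calibrated_image"))
  centres <- as.data.frame(centres)
  if (!all(c("row", "col") %in% names(centres))) {
    names(centres)[1:2] <- c("row", "col")
  }
  channels <- channels %||% names(image$channels)
  out <- list()
  for (i in seq_len(nrow(centres))) {
    id <- sprintf("pt_%d_%d", centres$row[i], centres$col[i])
    out <- c(out, sample_square(image, centres$row[i], centres$col[i],
                                half_size, channels, id))
  }
  out
}

#' Grid sampling scheme
#'
#' Square grid laid over a petal bounding box from which a fixed number of
#' cells is drawn pseudo-randomly: scheme A is a 4 x 3 grid (12 candidate
#' cells), scheme B a 6 x 2 grid, chosen so a single petal is fully
#' enclosed. Three cells are selected by default.
#'
#' @param scheme `"A"` (4 rows x 3 cols) or `"B"` (6 rows x 2 cols).
#' @param cell_size_px Cell edge in pixels (e.g. 40 for scheme A on a large
#'   petal, 30 for scheme B on a narrow one).
#' @param n_selected Number of cells drawn without replacement (default 3).
#' @param seed Integer seed for the draw.
#' @return Object of class `grid_scheme`.
#' @export
grid_scheme <- function(scheme = c("A", "B"), cell_size_px, n_selected = 3L, seed = 1L) {
  scheme <- match.arg(scheme)
  dims <- if (scheme == "A") c(4L, 3L) else c(6L, 2L)
  if (cell_size_px <= 0) stop("grid_scheme: cell_size_px must be positive")
  if (n_selected > prod(dims)) {
    stop("grid_scheme: n_selected exceeds the ", prod(dims), " available cells")
  }
  structure(list(scheme = scheme, rows = dims[1], cols = dims[2],
                 cell_size_px = as.integer(cell_size_px),
                 n_selected = as.integer(n_selected), seed = as.integer(seed)),
            class = "grid_scheme")
}

#' Pseudo-random grid sampling of a petal bounding box
#'
#' Lays the scheme's grid over the top-left corner of the bounding box and
#' draws `n_selected` distinct cells using the scheme's seed; each selected
#' cell becomes one [region_sample()] per channel.
#'
#' @param image A [calibrated_image()].
#' @param petal_bbox List `list(row = r0, col = c0)` giving the 0-based
#'   top-left corner of the grid (optionally `height`/`width` for
#'   validation).
#' @param scheme A [grid_scheme()].
#' @param channels Channels to sample (default all).
#' @return List of [region_sample()]; cell ids are `cell_<k>` with `k` the
#'   row-major cell index.
#' @export
grid_sample <- function(image, petal_bbox, scheme, channels = NULL) {
  stopifnot(inherits(image, "calibrated_image"), inherits(scheme, "grid_scheme"))
  channels <- channels %||% names(image$channels)
  d <- dim(image$channels[[1]])
  r0 <- petal_bbox$row; c0 <- petal_bbox$col
  need_h <- scheme$rows * scheme$cell_size_px
  need_w <- scheme$cols * scheme$cell_size_px
  if (r0 < 0 || c0 < 0 || r0 + need_h > d[1] || c0 + need_w > d[2]) {
    max_cell <- floor(min((d[1] - r0) / scheme$rows, (d[2] - c0) / scheme$cols))
    stop(sprintf("grid_sample: %dx%d grid of %d px cells does not fit at (%d, %d); max cell_size there is %d px",
                 scheme$rows, scheme$cols, scheme$cell_size_px, r0, c0, max_cell))
  }
  n_cells <- scheme$rows * scheme$cols
  picked <- withr::with_seed(scheme$seed, sample.int(n_cells, scheme$n_selected))
  out <- list()
  for (k in picked) {
    ri <- (k - 1) %/% scheme$cols   # row-major cell index
    cj <- (k - 1) %% scheme$cols
    rows <- (r0 + ri * scheme$cell_size_px) + seq_len(scheme$cell_size_px)
    cols <- (c0 + cj * scheme$cell_size_px) + seq_len(scheme$cell_size_px)
    for (ch in channels) {
      v <- image$channels[[ch]][rows, cols]
      bad <- image$flags[[ch]]$clipped[rows, cols] |
        image$flags[[ch]]$low_signal[rows, cols]
      out[[length(out) + 1]] <- region_sample(sprintf("cell_%d", k), ch,
                                              v[!bad], flags_excluded = sum(bad))
    }
  }
  out
}
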