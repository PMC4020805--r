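flat_cal <- function(value, n = 64, channel = "g", clipped = NULL, low = NULL) {
  clip <- clipped %||% matrix(FALSE, n, n)
  lows <- low %||% matrix(FALSE, n, n)
  chans <- stats::setNames(list(matrix(value, n, n)), channel)
  flags <- stats::setNames(list(list(clipped = clip, low_signal = lows)), channel)
  calibrated_image(chans, "reflectance", flags)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("point sampling a uniform image yields its value with zero spread and 225 pixels", {
  img <- flat_cal(0.4)
  s <- point_sample(img, data.frame(row = 30, col = 30))[[1]]
  expect_equal(s$mean, 0.4)
  expect_equal(s$sd, 0)
  expect_equal(s$pixel_count, 225)
  expect_equal(s$flags_excluded, 0L)
})

test_that("point sample mean equals an explicit pixel-loop oracle", {
  n <- 64
  vals <- matrix(seq(0, 1, length.out = n * n), n, n)
  img <- flat_cal(0, n); img$channels$g <- vals
  s <- point_sample(img, data.frame(row = 20, col = 33), half_size = 7)[[1]]
  acc <- 0; cnt <- 0
  for (r in (20 - 7):(20 + 7)) for (cc in (33 - 7):(33 + 7)) {
    acc <- acc + vals[r + 1, cc + 1]; cnt <- cnt + 1
  }
  expect_equal(s$mean, acc / cnt)
  expect_equal(s$pixel_count, cnt)
})

test_that("clipped pixels are excluded from the sample and counted", {
  n <- 64
  clip <- matrix(FALSE, n, n)
  clip[1:8, ] <- TRUE  # rows 0..7 of the 15x15 square centred at row 7
  img <- flat_cal(0.4, n, clipped = clip)
  s <- point_sample(img, data.frame(row = 7, col = 30))[[1]]
  expect_equal(s$flags_excluded, 8L * 15L)
  expect_equal(s$pixel_count, 225)
  expect_equal(length(s$values), 225 - 120)
  expect_equal(s$mean, 0.4)
})

test_that("point sampling outside the image names the offending centre", {
  img <- flat_cal(0.4, 32)
  expect_error(point_sample(img, data.frame(row = 3, col = 16)), "\\(3, 16\\)")
})

test_that("grid schemes expose the published layouts and validate parameters", {
  a <- grid_scheme("A", cell_size_px = 40)
  expect_equal(c(a$rows, a$cols), c(4L, 3L))
  expect_equal(a$n_selected, 3L)
  b <- grid_scheme("B", cell_size_px = 30)
  expect_equal(c(b$rows, b$cols), c(6L, 2L))
  expect_error(grid_scheme("A", 40, n_selected = 13), "12")
  expect_error(grid_scheme("A", 0), "positive")
})

test_that("grid sampling is deterministic per seed and exhaustive when all cells are drawn", {
  img <- flat_cal(0.5, 200)
  sch <- grid_scheme("A", 40, seed = 21)
  s1 <- grid_sample(img, list(row = 10, col = 10), sch)
  s2 <- grid_sample(img, list(row = 10, col = 10), sch)
  expect_identical(sample_report(s1), sample_report(s2))
  all12 <- grid_scheme("A", 40, n_selected = 12, seed = 5)
  s3 <- grid_sample(img, list(row = 10, col = 10), all12)
  expect_setequal(unique(vapply(s3, `[[`, character(1), "region_id")),
                  sprintf("cell_%d", 1:12))
})

test_that("a too-small bounding box errors with the maximum feasible cell size", {
  img <- flat_cal(0.5, 100)
  expect_error(grid_sample(img, list(row = 10, col = 10), grid_scheme("A", 40)),
               "max cell_size there is 22")
})

test_that("grid cell selection is uniform over the candidate cells", {
  img <- flat_cal(0.5, 200)
  counts <- integer(12)
  n_draws <- 10000
  for (s in seq_len(n_draws)) {
    sch <- grid_scheme("A", 40, seed = s)
    picked <- grid_sample(img, list(row = 10, col = 10), sch)
    ids <- as.integer(sub("cell_", "", vapply(picked, `[[`, character(1), "region_id")))
    counts[ids] <- counts[ids] + 1L
  }
  freq <- counts / n_draws
  expect_true(all(abs(freq - 3 / 12) <= 0.01))
})

test_that("the rank-sum comparison reproduces the exact enumeration oracle", {
  camera <- c(1, 2, 3); predicted <- c(10, 11, 12)
  res <- compare_methods(camera, predicted)
  expect_true(res$exact)
  expect_equal(res$p_value, 0.1)
  expect_equal(res$p_value, oracle_wilcoxon_p(camera, predicted))
  # a second configuration against the oracle
  x <- c(0.2, 0.5, 0.9, 1.4); y <- c(0.3, 0.6, 1.0)
  expect_equal(compare_methods(x, y)$p_value, oracle_wilcoxon_p(x, y))
})

test_that("the comparison is symmetric in its two sides", {
  withr::with_seed(3, {
    x <- rnorm(8); y <- rnorm(10, 0.5)
  })
  expect_equal(compare_methods(x, y)$p_value, compare_methods(y, x)$p_value)
})

test_that("degenerate all-tied input warns and reports the maximal p", {
  expect_warning(res <- compare_methods(rep(1, 5), rep(1, 5)), "tied")
  expect_equal(res$p_value, 1)
  expect_false(is.null(res$note))
})

test_that("comparison requires 3 values per side and accepts region samples", {
  expect_error(compare_methods(c(1, 2), c(3, 4, 5)), "at least 3")
  rs <- lapply(1:4, function(i) region_sample(paste0("r", i), "g", c(i, i + 0.1, i + 0.2)))
  res <- compare_methods(rs, c(10, 11, 12), mode = "means")
  expect_equal(res$n_camera, 4)
  res2 <- compare_methods(rs, c(10, 11, 12), mode = "pixels")
  expect_equal(res2$n_camera, 12)
})

test_that("per-channel comparison adds a Holm-adjusted column", {
  withr::with_seed(9, {
    cam <- list(red = rnorm(6, 1), green = rnorm(6, 0.5), blue = rnorm(6, 0.5))
    pred <- list(red = rnorm(6, 0.2), green = rnorm(6, 0.5), blue = rnorm(6, 0.5))
  })
  df <- compare_methods_by_channel(cam, pred)
  expect_equal(nrow(df), 3)
  expect_true(all(df$p_holm >= df$p_value))
})

test_that("normality checks behave on normal, bimodal, constant and tiny samples", {
  withr::with_seed(14, {
    normal <- rnorm(500)
    bimodal <- c(rnorm(250, -2, 0.3), rnorm(250, 2, 0.3))
  })
  expect_gt(normality_check(normal)$p_value, 0.05)
  expect_lt(normality_check(bimodal)$p_value, 0.05)
  expect_error(normality_check(rep(0.4, 10)), "constant")
  expect_error(normality_check(c(1, 2)), "\\[3, 5000\\]")
})

test_that("variability summary ranks channel dispersion and declares exact ties", {
  mk <- function(ch, vals_list) lapply(seq_along(vals_list), function(i) {
    region_sample(paste0("r", i), ch, vals_list[[i]])
  })
  samples <- list(
    red = mk("red", list(c(0.2, 0.8, 0.5), c(0.1, 0.9, 0.3))),
    uv = mk("uv", list(c(0.40, 0.41, 0.42), c(0.40, 0.42, 0.41))))
  vs <- variability_summary(samples)
  expect_equal(vs$table$dispersion_rank[vs$table$channel == "red"], 1L)
  expect_equal(vs$table$dispersion_rank[vs$table$channel == "uv"], 2L)
  # identical data in all channels: tied ranking
  same <- list(a = mk("a", list(1:3 / 10, 4:6 / 10)), b = mk("b", list(1:3 / 10, 4:6 / 10)))
  expect_true(all(variability_summary(same)$table$dispersion_rank == 1L))
  expect_error(variability_summary(list(a = mk("a", list(1:3 / 10)))), "at least 2")
})

test_that("region sample bookkeeping matches its invariant", {
  s <- region_sample("r", "g", c(0.1, 0.2, 0.3), flags_excluded = 5)
  expect_equal(s$pixel_count, length(s$values) + s$flags_excluded)
  df <- sample_report(s)
  expect_equal(df$n, 8)
  expect_equal(df$excluded, 5)
})
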