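test_that("transfer-function construction rejects invalid shapes and flags range drift", {
  expect_error(transfer_function("single_exp", c(a = 0.1, b = -2)), "increasing")
  expect_error(transfer_function("single_exp", c(a = 0.5, b = 2)), "1.5")
  expect_error(transfer_function("biexponential", c(0.1, 2)), "4 coefficients")
  expect_silent(transfer_function("biexponential",
                                  c(0.515604, 0.690511, -0.507550, -8.739707)))
  # a mild overshoot of full scale is tolerated but flagged
  expect_warning(tf <- transfer_function("single_exp", c(a = 0.09, b = 2.5)), "flagged")
  expect_true(tf$out_of_bounds)
})

test_that("a noiseless single-exponential series is recovered exactly and auto-selected", {
  tf0 <- transfer_function("single_exp", c(a = 0.08, b = 2.5))
  series <- make_grey_series(tf0, n_steps = 12)
  fit <- fit_transfer(series, form = "auto")
  expect_equal(fit$form, "single_exp")
  expect_equal(unname(fit$coefficients), c(0.08, 2.5), tolerance = 1e-6)
})

test_that("a noiseless biexponential series is recovered and auto-selected", {
  tf0 <- transfer_function("biexponential",
                           c(a = 0.515604, b = 0.690511, c = -0.507550, d = -8.739707))
  series <- make_grey_series(tf0, n_steps = 14)
  fit <- fit_transfer(series, form = "auto")
  expect_equal(fit$form, "biexponential")
  expect_equal(unname(fit$coefficients),
               c(0.515604, 0.690511, -0.507550, -8.739707), tolerance = 1e-4)
})

test_that("transfer fitting validates its input series", {
  tf0 <- transfer_function("single_exp", c(a = 0.08, b = 2.5))
  s <- make_grey_series(tf0, n_steps = 12)
  expect_error(fit_transfer(s[1:5, ]), "at least 6")
  s2 <- s; s2$rel_exposure <- s2$rel_exposure * 0.5
  expect_error(fit_transfer(s2), "0.95")
  expect_error(fit_transfer(data.frame(x = 1, y = 2)), "columns")
})

test_that("coefficient confidence intervals cover the truth at the nominal rate", {
  truth <- c(0.515604, 0.690511, -0.507550, -8.739707)
  tf0 <- transfer_function("biexponential", truth)
  x <- 10^seq(log10(0.02), 0, length.out = 16)
  q0 <- tf_eval(tf0, x)
  covered <- withr::with_seed(2024, {
    vapply(1:100, function(i) {
      q <- q0 * (1 + stats::rnorm(length(x), 0, 0.05))
      fit <- tryCatch(fit_transfer(data.frame(rel_exposure = x, mean_pixel = q,
                                              sd_pixel = 0.05 * q0),
                                   form = "biexponential"),
                      error = function(e) NULL)
      if (is.null(fit)) return(NA_integer_)
      ci <- fit$ci95
      sum(truth >= ci$lower & truth <= ci$upper)
    }, numeric(1))
  })
  ok <- sum(covered >= 3, na.rm = TRUE)
  # binomial(100, ~0.95): central 99% range
  expect_gte(ok, 88)
})

test_that("inverting the identity transfer gives entry[p] = p/255 exactly", {
  lut <- invert_to_lut(transfer_function("identity"), n_boot = 0)
  expect_equal(lut$entries, (0:255) / 255, tolerance = 1e-9)
  expect_true(all(diff(lut$entries) >= 0))
})

test_that("LUT entries are non-decreasing and self-consistent under the forward map", {
  for (tf in list(transfer_function("single_exp", c(a = 0.08, b = 2.5)),
                  transfer_function("biexponential",
                                    c(0.515604, 0.690511, -0.507550, -8.739707)))) {
    lut <- invert_to_lut(tf, n_boot = 0)
    expect_true(all(diff(lut$entries) >= 0))
    inv <- which(lut$flag %in% c("ok", "low_signal")) - 1L
    back <- tf_eval(tf, lut$entries[inv + 1L]) * 255
    expect_lt(max(abs(back - inv)), 0.5)
  }
})

test_that("out-of-range LUT targets are clamped and flagged", {
  tf <- transfer_function("single_exp", c(a = 0.08, b = 2.5))  # f(0)=0.08, f(1)<1
  lut <- invert_to_lut(tf, n_boot = 0)
  below <- 0:floor(0.08 * 255)
  expect_true(all(lut$flag[below + 1] == "clamped_low"))
  expect_true(all(lut$entries[below + 1] == 0))
  expect_equal(lut$flag[256], "clamped_high")
  expect_equal(lut$entries[256], 1)
})

test_that("LUT relative uncertainty is larger at low levels than mid-range", {
  tf0 <- transfer_function("biexponential",
                           c(0.515604, 0.690511, -0.507550, -8.739707))
  series <- withr::with_seed(5, {
    x <- 10^seq(log10(0.02), 0, length.out = 16)
    q0 <- tf_eval(tf0, x)
    data.frame(rel_exposure = x, mean_pixel = q0 * (1 + stats::rnorm(16, 0, 0.02)),
               sd_pixel = 0.02 * q0)
  })
  fit <- fit_transfer(series, form = "biexponential")
  lut <- invert_to_lut(fit, n_boot = 1000, seed = 10)
  # a gamma-like toe is steep, so the absolute SD of the inverse is small at
  # low levels; the reliability statement is about the SD relative to the
  # recovered value, which is largest where the signal is weakest
  expect_gt(lut$rel_uncertainty[10 + 1], lut$rel_uncertainty[128 + 1])
  expect_gt(lut$rel_uncertainty[10 + 1], 2 * lut$rel_uncertainty[128 + 1])
})

test_that("LUT bootstrap is reproducible under a fixed seed", {
  tf0 <- transfer_function("biexponential",
                           c(0.515604, 0.690511, -0.507550, -8.739707))
  series <- make_grey_series(tf0, n_steps = 14)
  fit <- fit_transfer(series, form = "biexponential")
  l1 <- invert_to_lut(fit, n_boot = 200, seed = 3)
  l2 <- invert_to_lut(fit, n_boot = 200, seed = 3)
  expect_identical(l1$uncertainty, l2$uncertainty)
})

test_that("linearising through the identity LUT returns p/255 with no flags below 245", {
  lut <- invert_to_lut(transfer_function("identity"), n_boot = 0)
  img <- array(rep(30:245, length.out = 16 * 16), dim = c(16, 16, 1),
               dimnames = list(NULL, NULL, "green"))
  lin <- linearise_image(img, list(green = lut))
  expect_equal(lin$channels$green, img[, , 1] / 255, tolerance = 1e-9)
  expect_false(any(lin$flags$green$clipped))
  expect_false(any(lin$flags$green$low_signal[img[, , 1] >= 24]))
})

test_that("linearisation rejects non-8-bit input", {
  lut <- invert_to_lut(transfer_function("identity"), n_boot = 0)
  img <- array(c(100, 300, 10, 20), dim = c(2, 2, 1), dimnames = list(NULL, NULL, "g"))
  expect_error(linearise_image(img, list(g = lut)), "8-bit")
  img2 <- array(c(0.5, 0.2, 0.1, 0.9), dim = c(2, 2, 1), dimnames = list(NULL, NULL, "g"))
  expect_error(linearise_image(img2, list(g = lut)), "8-bit")
})

test_that("render-then-linearise round-trips linear exposure within one level for mid-range input", {
  tf <- transfer_function("biexponential",
                          c(0.515604, 0.690511, -0.507550, -8.739707))
  lut <- invert_to_lut(tf, n_boot = 0)
  # ground truth exposure ladder through the forward transfer + quantisation
  x <- seq(0.1, 0.96, length.out = 40)
  p <- pmin(pmax(round(255 * tf_eval(tf, x)), 0), 255)
  keep <- p >= 24 & p <= 244
  rec <- lut$entries[p + 1L]
  expect_lt(max(abs(rec[keep] - x[keep])), 1 / 255)
})

test_that("linearised images are darker than their non-linear counterparts for a gamma-like transfer", {
  cam <- test_visible_camera()
  fx <- make_flower_scene("bullseye", seed = 6)
  fr <- render_scene(fx$scene, cam)
  luts <- lapply(cam$transfers, invert_to_lut, n_boot = 0)
  lin <- linearise_image(fr, luts)
  for (ch in names(lin$channels)) {
    expect_lte(mean(lin$channels[[ch]]), mean(fr$image[, , ch] / 255))
  }
})

test_that("LUT and characterisation-series CSV round-trips preserve content", {
  tf <- transfer_function("single_exp", c(a = 0.08, b = 2.5))
  lut <- invert_to_lut(tf, n_boot = 0)
  p <- withr::local_tempfile(fileext = ".csv")
  write_lut_csv(lut, p)
  lut2 <- read_lut_csv(p)
  expect_equal(lut2$entries, lut$entries)
  expect_equal(lut2$flag, lut$flag)
  s <- make_grey_series(tf, n_steps = 10)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_series_csv(s, p2)
  expect_equal(read_series_csv(p2)$mean_pixel, s$mean_pixel)
})
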