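make_lin_frame <- function(cam, scene, noise = no_noise(), seed = 1) {
  fr <- render_scene(scene, cam, noise = noise, seed = seed)
  luts <- lapply(cam$transfers, invert_to_lut, n_boot = 0)
  list(frame = fr, lin = linearise_image(fr, luts))
}

test_that("standard specs validate nominal reflectance and ROI", {
  expect_error(standard_spec("white", 0, list(rows = 1:2, cols = 1:2)), "\\(0, 1\\]")
  expect_error(standard_spec("white", 1.2, list(rows = 1:2, cols = 1:2)), "\\(0, 1\\]")
  expect_error(standard_spec("white", 0.9, matrix(FALSE, 3, 3)), "empty")
})

test_that("a grey standard reading its nominal linear value gives scale 1", {
  lin <- calibrated_image(
    list(g = matrix(0.33, 10, 10)), "linear",
    list(g = list(clipped = matrix(FALSE, 10, 10), low_signal = matrix(FALSE, 10, 10))))
  st <- standard_spec("grey_33", 0.33, list(rows = 1:10, cols = 1:10))
  sc <- calibrate_exposure(lin, list(st))
  expect_equal(unname(sc["g"]), 1.0)
})

test_that("recovered reflectance is invariant to a global exposure change", {
  cam <- test_visible_camera()
  fx <- make_flower_scene("plain", seed = 8)
  full <- make_lin_frame(cam, fx$scene)
  half_cam <- cam
  half_cam$exposure$scale_per_channel <- cam$exposure$scale_per_channel / 2
  half <- make_lin_frame(half_cam, fx$scene)
  white <- fx$standards[[1]]
  sc_full <- calibrate_exposure(full$lin, list(white))
  sc_half <- calibrate_exposure(half$lin, list(white))
  # halving exposure doubles the scale factor
  expect_equal(as.numeric(sc_half) / as.numeric(sc_full), rep(2, 3), tolerance = 0.02)
  r_full <- to_reflectance(full$lin, sc_full)
  r_half <- to_reflectance(half$lin, sc_half)
  grey <- fx$standards[[2]]$roi
  for (ch in names(r_full$channels)) {
    m_full <- mean(r_full$channels[[ch]][grey$rows, grey$cols])
    m_half <- mean(r_half$channels[[ch]][grey$rows, grey$cols])
    expect_lt(abs(m_full - m_half), 0.01)
  }
})

test_that("the white standard renders at the 245-level exposure contract", {
  cam <- test_visible_camera()
  fx <- make_flower_scene("plain", seed = 9)
  fr <- render_scene(fx$scene, cam)
  white <- fx$standards[[1]]$roi
  for (ch in dimnames(fr$image)[[3]]) {
    expect_equal(max(fr$image[white$rows, white$cols, ch]), 245)
  }
})

test_that("multiple standards are combined and clipped standards excluded", {
  n <- 10
  plane <- matrix(0.5, n, n)
  plane[, 1:5] <- 0.33          # grey patch reads its truth
  plane[, 6:10] <- 0.95         # white patch reads its truth
  clip <- matrix(FALSE, n, n)
  lin <- calibrated_image(list(g = plane), "linear",
                          list(g = list(clipped = clip, low_signal = matrix(FALSE, n, n))))
  grey <- standard_spec("grey_33", 0.33, list(rows = 1:n, cols = 1:5))
  white <- standard_spec("checker_white", 0.95, list(rows = 1:n, cols = 6:10))
  sc <- calibrate_exposure(lin, list(grey, white))
  expect_equal(unname(sc["g"]), 1.0, tolerance = 1e-12)
  # now clip the white patch: calibration must still work off the grey
  clip2 <- clip; clip2[, 6:10] <- TRUE
  lin2 <- calibrated_image(list(g = plane * 2), "linear",
                           list(g = list(clipped = clip2, low_signal = matrix(FALSE, n, n))))
  sc2 <- calibrate_exposure(lin2, list(grey, white))
  expect_equal(unname(sc2["g"]), 0.5, tolerance = 1e-12)
  # all standards clipped: error
  clip3 <- clip; clip3[] <- TRUE
  lin3 <- calibrated_image(list(g = plane), "linear",
                           list(g = list(clipped = clip3, low_signal = matrix(FALSE, n, n))))
  expect_error(calibrate_exposure(lin3, list(grey, white)), "no usable")
})

test_that("end-to-end recovery returns the nominal reflectance of in-frame standards", {
  cam <- test_visible_camera()
  fx <- make_flower_scene("bullseye", seed = 10)
  got <- make_lin_frame(cam, fx$scene)
  sc <- calibrate_exposure(got$lin, list(fx$standards[[1]]))
  refl <- to_reflectance(got$lin, sc)
  grey <- fx$standards[[2]]$roi
  checker <- fx$standards[[3]]$roi
  for (ch in names(refl$channels)) {
    expect_lt(abs(mean(refl$channels[[ch]][grey$rows, grey$cols]) - 0.33), 0.02)
    expect_lt(abs(mean(refl$channels[[ch]][checker$rows, checker$cols]) - 0.95), 0.02)
  }
})

test_that("a spectrally flat region recovers equal reflectance across channels within 2%", {
  cam <- test_visible_camera()
  fx <- make_flower_scene("bullseye", seed = 12)
  got <- make_lin_frame(cam, fx$scene)
  sc <- calibrate_exposure(got$lin, list(fx$standards[[1]]))
  refl <- to_reflectance(got$lin, sc)
  grey <- fx$standards[[2]]$roi
  means <- vapply(names(refl$channels), function(ch) {
    mean(refl$channels[[ch]][grey$rows, grey$cols])
  }, numeric(1))
  expect_lt(max(means) - min(means), 0.02)
})

test_that("reflectance conversion propagates flags and scales uncertainty", {
  n <- 4
  clip <- matrix(c(TRUE, rep(FALSE, n * n - 1)), n, n)
  lin <- calibrated_image(list(g = matrix(0.2, n, n)), "linear",
                          list(g = list(clipped = clip, low_signal = matrix(FALSE, n, n))),
                          uncertainty = list(g = matrix(0.01, n, n)))
  refl <- to_reflectance(lin, c(g = 2))
  expect_equal(refl$channels$g, matrix(0.4, n, n))
  expect_equal(refl$uncertainty$g, matrix(0.02, n, n))
  expect_identical(refl$flags$g$clipped, clip)
  expect_error(to_reflectance(refl, c(g = 2)), "not on the linear scale")
  expect_error(to_reflectance(lin, c(h = 2)), "missing")
})

test_that("the saturation diagnostic flags vendor-boosted channels only", {
  h <- 40; w <- 60
  img <- array(0L, dim = c(h, w, 2), dimnames = list(NULL, NULL, c("red", "green")))
  white_roi <- list(rows = 1:40, cols = 1:20)
  sample_roi <- list(rows = 1:40, cols = 21:40)
  clipped_roi <- list(rows = 1:40, cols = 41:60)
  img[white_roi$rows, white_roi$cols, ] <- 220L
  img[sample_roi$rows, sample_roi$cols, "red"] <- 242L   # 10% above white
  img[sample_roi$rows, sample_roi$cols, "green"] <- 180L
  img[clipped_roi$rows, clipped_roi$cols, ] <- 250L
  white <- standard_spec("checker_white", 0.95, white_roi)
  rep <- saturation_check(img, list(white),
                          list(sample = sample_roi, hot = clipped_roi))
  expect_equal(rep$status[rep$region == "sample" & rep$channel == "red"], "boosted")
  expect_equal(rep$status[rep$region == "sample" & rep$channel == "green"], "ok")
  expect_true(all(rep$status[rep$region == "hot"] == "clipped"))
  # all regions below the white level: empty of warnings
  img2 <- img; img2[sample_roi$rows, sample_roi$cols, "red"] <- 200L
  rep2 <- saturation_check(img2, list(white), list(sample = sample_roi))
  expect_true(all(rep2$status == "ok"))
})
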