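# Phantom rendering and circular-ROI measurement.

test_that("a noise-free slice paints the lumen exactly", {
  slc <- render_slice(phantom_geometry(), lumen_hu = 200, noise_sd = 0)
  expect_true(all(slc$pixels[slc$lumen_mask] == 200))
  expect_true(all(slc$pixels[!slc$lumen_mask] == 40))
  expect_identical(slc$true_lumen_mask, slc$lumen_mask)
})

test_that("the thrombus ring sits between lumen and background", {
  g <- phantom_geometry(thrombus_outer_mm = 22, thrombus_hu = 55)
  slc <- render_slice(g, lumen_hu = 300, noise_sd = 0)
  expect_setequal(unique(as.vector(slc$pixels)), c(40, 55, 300))
  expect_error(phantom_geometry(thrombus_outer_mm = 10),
               "exceed the lumen radius")
  expect_error(phantom_geometry(lumen_radius_mm = 60), "exceeds the .*grid")
})

test_that("dissection mode splits the lumen at the requested area fraction", {
  g <- phantom_geometry(dissection = TRUE, true_lumen_fraction = 0.3,
                        flap_thickness_mm = 1.4, false_lumen_hu = 90)
  slc <- render_slice(g, lumen_hu = 250, noise_sd = 0)
  true_n <- sum(slc$true_lumen_mask)
  lumen_n <- sum(slc$lumen_mask)
  expect_gt(true_n, 0)
  expect_lt(true_n, lumen_n)
  # the flap consumes some area; side fractions are checked against the
  # analytic segment area with a pixelation + flap allowance
  expect_equal(true_n / lumen_n, 0.3, tolerance = 0.12)
  expect_true(all(slc$pixels[slc$true_lumen_mask] == 250))
  false_mask <- slc$lumen_mask & !slc$true_lumen_mask &
    slc$pixels != g$flap_hu
  expect_true(all(slc$pixels[false_mask] == 90))
  expect_error(phantom_geometry(dissection = TRUE, true_lumen_fraction = 1),
               "strictly in")
})

test_that("rendering with noise is seeded and unbiased", {
  g <- phantom_geometry()
  a <- render_slice(g, 200, noise_sd = 15, seed = 1)
  b <- render_slice(g, 200, noise_sd = 15, seed = 1)
  expect_identical(a$pixels, b$pixels)
  expect_error(render_slice(g, 200, noise_sd = 15), "seed")
  roi <- auto_place_roi(a)
  m <- measure_roi(a, roi)
  expect_gt(m$n_pixels, 500)
  expect_lt(abs(m$mean_hu - 200), 3 * 15 / sqrt(m$n_pixels))
  # measured sd converges to the injected noise sd on a uniform region
  expect_equal(m$sd_hu, 15, tolerance = 0.15)
})

# helper: largest centroid-centred circle inside the true-lumen mask
min_dist_to_outside <- function(slc) {
  sp <- slc$geometry$pixel_spacing_mm
  idx <- which(slc$true_lumen_mask, arr.ind = TRUE)
  cy <- (mean(idx[, "row"]) - 1) * sp
  cx <- (mean(idx[, "col"]) - 1) * sp
  out <- which(!slc$true_lumen_mask, arr.ind = TRUE)
  min(sqrt(((out[, "col"] - 1) * sp - cx)^2 +
             ((out[, "row"] - 1) * sp - cy)^2))
}

test_that("automatic ROI placement is central, deterministic, and guarded", {
  g <- phantom_geometry()
  slc <- render_slice(g, 150, noise_sd = 0)
  roi <- auto_place_roi(slc)
  expect_equal(roi$center_mm, g$center_mm, tolerance = 1e-6)
  expect_equal(roi$radius_mm, 0.6 * min_dist_to_outside(slc), tolerance = 1e-9)
  # same geometry, different noise seeds -> identical placement
  roi2 <- auto_place_roi(render_slice(g, 150, noise_sd = 10, seed = 3))
  roi3 <- auto_place_roi(render_slice(g, 150, noise_sd = 10, seed = 4))
  expect_identical(roi2[c("center_mm", "radius_mm")],
                   roi3[c("center_mm", "radius_mm")])
  # a sliver of a true lumen cannot host the minimum ROI
  tiny <- phantom_geometry(dissection = TRUE, true_lumen_fraction = 0.04,
                           lumen_radius_mm = 8)
  expect_error(auto_place_roi(render_slice(tiny, 200, noise_sd = 0)),
               "too small")
})

test_that("the dissection ROI stays on the true-lumen side of the flap", {
  g <- phantom_geometry(dissection = TRUE, true_lumen_fraction = 0.3,
                        lumen_radius_mm = 18)
  slc <- render_slice(g, 220, noise_sd = 0)
  roi <- auto_place_roi(slc)
  m <- measure_roi(slc, roi)
  expect_equal(m$mean_hu, 220)   # only true-lumen pixels inside the ROI
  expect_identical(m$sd_hu, 0)
})

test_that("measure_roi matches a brute-force pixel enumeration", {
  g <- phantom_geometry(grid_size = 48, lumen_radius_mm = 8,
                        pixel_spacing_mm = 0.7)
  slc <- render_slice(g, 180, noise_sd = 20, seed = 12)
  roi <- auto_place_roi(slc)
  fast <- measure_roi(slc, roi)
  brute <- brute_measure_roi(slc, roi)
  expect_identical(fast$n_pixels, brute$n_pixels)
  expect_equal(fast$mean_hu, brute$mean_hu, tolerance = 1e-12)
  expect_equal(fast$sd_hu, brute$sd_hu, tolerance = 1e-12)
})

test_that("ROI validation rejects empty or out-of-grid discs", {
  slc <- render_slice(phantom_geometry(), 100, noise_sd = 0)
  expect_error(measure_roi(slc, list(center_mm = c(2, 2), radius_mm = 30)),
               "outside the pixel grid")
  # a sub-pixel disc between pixel centres catches no centre
  expect_error(measure_roi(slc, list(center_mm = c(40.35, 40.35),
                                     radius_mm = 0.1)),
               "no pixel centres")
})

test_that("round-trip bias vanishes as noise vanishes, dissection included", {
  for (g in list(phantom_geometry(),
                 phantom_geometry(dissection = TRUE,
                                  true_lumen_fraction = 0.4))) {
    bias <- vapply(c(20, 2, 0), function(sd) {
      slc <- render_slice(g, 199.9, noise_sd = sd,
                          seed = if (sd > 0) 31 else NULL)
      abs(measure_roi(slc, auto_place_roi(slc))$mean_hu - 199.9)
    }, numeric(1))
    expect_identical(bias[3], 0)
    expect_lt(bias[2], bias[1] + 1e-9)
    expect_lt(bias[1], 3)
  }
})

test_that("slice export writes a lossless CSV dump", {
  slc <- render_slice(phantom_geometry(grid_size = 32, lumen_radius_mm = 6),
                      123.456, noise_sd = 0)
  path <- withr::local_tempfile(fileext = ".csv")
  write_slice_csv(slc, path)
  back <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(back) <- NULL
  expect_equal(back, slc$pixels, tolerance = 1e-12)
})
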