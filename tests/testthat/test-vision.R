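ph_ref <- make_reference_phantom()

test_that("rendered scenes are deterministic and differ exactly on the sample", {
  sc <- render_scene_image(ph_ref, c(0, 0, 0), c(320, 320), 0.5, seed = 4,
                           sensor_noise_sd = 0)
  sc2 <- render_scene_image(ph_ref, c(0, 0, 0), c(320, 320), 0.5, seed = 4,
                            sensor_noise_sd = 0)
  expect_identical(sc, sc2)
  d <- abs(sc$sample - sc$background) > 0
  # noiseless difference is exactly the axis-aligned footprint rectangle
  idx <- which(d, arr.ind = TRUE)
  xr <- range((idx[, 2] - 0.5) * 0.5); yr <- range((idx[, 1] - 0.5) * 0.5)
  expect_equal(diff(xr), 100, tolerance = 0.5)   # +/- one pixel
  expect_equal(diff(yr), 60, tolerance = 0.5)
  expect_equal(sum(d) * 0.5^2, 6000, tolerance = 0.02 * 6000)
  # rotation preserves the rasterised area within 2%
  sc30 <- render_scene_image(ph_ref, c(0, 0, 30), c(320, 320), 0.5, seed = 4,
                             sensor_noise_sd = 0)
  a30 <- sum(abs(sc30$sample - sc30$background) > 0) * 0.5^2
  expect_equal(a30, sum(d) * 0.5^2, tolerance = 0.02 * 6000)
  expect_error(render_scene_image(ph_ref, c(120, 0, 0)), "frame")
})

test_that("background subtraction recovers area and orientation", {
  sc <- render_scene_image(ph_ref, c(3, -2, 30), c(320, 320), 0.5, seed = 5)
  m <- subtract_background(sc)
  expect_s3_class(m, "sample_mask")
  expect_equal(m$area_mm2, 6000, tolerance = 0.02 * 6000)
  expect_equal(m$principal_angle, 30, tolerance = 1)
  sc0 <- render_scene_image(ph_ref, c(0, 0, 0), c(320, 320), 0.5, seed = 5)
  m0 <- subtract_background(sc0)
  expect_equal(m0$principal_angle, 0, tolerance = 1)
  # identical sample and background: nothing to detect
  expect_error(subtract_background(sc$background, sc$background,
                                   mm_per_pixel = 0.5), "no sample")
})

test_that("orientation normalisation zeroes the angle and preserves area", {
  sc <- render_scene_image(ph_ref, c(0, 3, 17), c(320, 320), 0.5, seed = 6)
  m <- subtract_background(sc)
  mn <- normalize_orientation(m)
  expect_lt(abs(mn$principal_angle), 1)
  expect_equal(mn$area_mm2, m$area_mm2, tolerance = 0.02 * m$area_mm2)
  expect_equal(mn$applied_rotation, 17, tolerance = 1)
  # an already-aligned mask passes through unchanged
  m0 <- subtract_background(render_scene_image(ph_ref, c(0, 0, 0),
                                               c(320, 320), 0.5, seed = 6))
  expect_identical(normalize_orientation(m0)$mask, m0$mask)
})

test_that("lattice count on a 10 x 10 mm square mask matches brute force", {
  # pixel centres span [0, 10] mm at 0.5 mm/px inside a padded frame
  full <- matrix(FALSE, 60, 60)
  full[20:40, 20:40] <- TRUE
  mask <- nodulecad:::new_sample_mask(full, 0.5)
  g <- build_indentation_grid(mask, step = 2, margin = 0)
  expect_identical(nrow(g$points), 36L)   # 6 x 6 inclusive lattice
  expect_true(all(abs(g$points$x %% 2) < 0.2))
  # doubling the step reduces the point count
  g4 <- build_indentation_grid(mask, step = 4, margin = 0)
  expect_lt(nrow(g4$points), nrow(g$points))
  expect_error(build_indentation_grid(mask, step = 25, margin = 12),
               "too small")
})

test_that("margin keeps every grid point clear of the mask border", {
  sc <- render_scene_image(ph_ref, c(0, 0, 0), c(320, 320), 0.5, seed = 7)
  mn <- normalize_orientation(subtract_background(sc))
  g <- build_indentation_grid(mn, step = 2, margin = 1.5)
  bg <- which(!mn$mask, arr.ind = TRUE)
  bx <- (bg[, 2] - 0.5) * 0.5; by <- (bg[, 1] - 0.5) * 0.5
  for (i in seq_len(nrow(g$points))) {
    x <- g$points$x[i] + g$origin_mm[["x"]]
    y <- g$points$y[i] + g$origin_mm[["y"]]
    expect_gte(min(sqrt((bx - x)^2 + (by - y)^2)), 1.5)
  }
})

test_that("grid is invariant to the rendering pose after normalisation", {
  g_ref <- build_indentation_grid(normalize_orientation(
    subtract_background(render_scene_image(ph_ref, c(0, 0, 0),
                                           c(320, 320), 0.5, seed = 8))))
  set.seed(99)
  for (rep in 1:3) {
    pose <- c(runif(2, -6, 6), runif(1, -30, 30))
    g <- build_indentation_grid(normalize_orientation(
      subtract_background(render_scene_image(ph_ref, pose, c(320, 320), 0.5,
                                             seed = 8 + rep))))
    expect_identical(nrow(g$points), nrow(g_ref$points))
    a <- g$points[order(g$points$x, g$points$y), ]
    b <- g_ref$points[order(g_ref$points$x, g_ref$points$y), ]
    expect_lt(max(abs(a$x - b$x)), 0.25)   # half a pixel
    expect_lt(max(abs(a$y - b$y)), 0.25)
  }
})
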