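test_that("reflection coefficient: identities, printed-impedance value, symmetry", {
  expect_identical(reflection_coefficient_intensity(1.59, 1.59), 0)
  # healthy vs tumor agar: ((1.92 - 1.59) / (1.92 + 1.59))^2
  r <- reflection_coefficient_intensity(healthy_material(), tumor_material())
  expect_equal(r, (0.33 / 3.51)^2, tolerance = 1e-12)
  expect_lt(r, 0.01)
  expect_identical(reflection_coefficient_intensity(1.2, 2.5),
                   reflection_coefficient_intensity(2.5, 1.2))
  expect_error(reflection_coefficient_intensity(-1, 2), "positive")
})

test_that("reflection coefficient lies in [0, 1) and vanishes iff impedances match", {
  set.seed(42)
  for (i in 1:50) {
    z <- runif(2, 0.1, 10)
    r <- reflection_coefficient_intensity(z[1], z[2])
    expect_gte(r, 0)
    expect_lt(r, 1)
    expect_identical(r == 0, z[1] == z[2])
  }
})

test_that("vertical chord follows sphere geometry", {
  ph <- phantom(inclusions = list(inclusion(c(50, 30, 7.5), 12)))
  expect_equal(inclusion_chord(ph, 50, 30), 12)
  expect_equal(inclusion_chord(ph, 56, 30), 0)          # tangent: d = r
  ph6 <- phantom(inclusions = list(inclusion(c(50, 30, 7.5), 12)))
  expect_equal(inclusion_chord(ph6, 53, 30), 2 * sqrt(36 - 9), tolerance = 1e-12)
  expect_error(inclusion_chord(ph, -1, 30), "footprint")
  expect_length(inclusion_chord(phantom(), 10, 10), 0)
})

test_that("homogenised stiffness recovers pure materials and is bounded", {
  expect_equal(local_stiffness(phantom(), 50, 30), 0.33)
  tum <- phantom(matrix_material = tumor_material())
  expect_equal(local_stiffness(tum, 50, 30), 4.6)
  ph <- make_reference_phantom()
  for (pt in list(c(15, 18), c(40, 18), c(82, 18), c(33, 25))) {
    k <- local_stiffness(ph, pt[1], pt[2])
    expect_gte(k, 0.33)
    expect_lte(k, 4.6)
  }
  expect_error(local_stiffness(ph, 200, 18), "footprint")
})

test_that("stiffness increases with inclusion diameter at fixed depth", {
  ks <- vapply(seq(1, 13, by = 1), function(d) {
    ph <- phantom(inclusions = list(inclusion(c(50, 30, 7.5), d)))
    local_stiffness(ph, 50, 30)
  }, numeric(1))
  expect_true(all(diff(ks) > 0))
  # larger sphere reads stiffer than a smaller one at the same depth
  expect_gt(ks[12], ks[3])
})

test_that("reference phantom has the prescribed inclusion set and geometry", {
  ph <- make_reference_phantom(seed = 0, randomize_positions = FALSE)
  expect_s3_class(ph, "phantom")
  expect_identical(c(ph$length_mm, ph$width_mm, ph$thickness_mm),
                   c(100, 60, 15))
  d <- sort(vapply(ph$inclusions, `[[`, numeric(1), "diameter"))
  expect_identical(d, c(3, 3, 6, 6, 9, 9, 12, 12))
  expect_equal(ph$matrix_material$stiffness, 0.33)
  expect_equal(ph$inclusions[[1]]$material$stiffness, 4.6)
  # deterministic field-for-field
  expect_identical(make_reference_phantom(seed = 7, randomize_positions = TRUE),
                   make_reference_phantom(seed = 7, randomize_positions = TRUE))
  zb <- vapply(make_reference_phantom(bury_small = TRUE)$inclusions,
               function(i) i$center[3], numeric(1))
  db <- vapply(ph$inclusions, `[[`, numeric(1), "diameter")
  expect_true(all(zb[db <= 6] == 10) && all(zb[db >= 9] == 7.5))
})

test_that("randomised placement respects separation and clearance over many seeds", {
  for (seed in 1:100) {
    ph <- make_reference_phantom(seed = seed, randomize_positions = TRUE)
    ctr <- t(vapply(ph$inclusions, `[[`, numeric(3), "center"))
    r <- vapply(ph$inclusions, `[[`, numeric(1), "diameter") / 2
    # containment (also enforced by the constructor)
    expect_true(all(ctr[, 1] - r >= 5 - 1e-9 &
                    ctr[, 1] + r <= 100 - 5 + 1e-9))
    expect_true(all(ctr[, 2] - r >= 5 - 1e-9 &
                    ctr[, 2] + r <= 60 - 5 + 1e-9))
    expect_true(all(ctr[, 3] - r >= 0 & ctr[, 3] + r <= 15))
    for (i in 1:7) for (j in (i + 1):8) {
      gap <- sqrt(sum((ctr[i, 1:2] - ctr[j, 1:2])^2)) - r[i] - r[j]
      expect_gte(gap, 10 - 1e-9)
    }
  }
})

test_that("phantom constructor rejects escaping or overlapping inclusions", {
  expect_error(phantom(inclusions = list(inclusion(c(2, 30, 7.5), 12))),
               "contained")
  expect_error(
    phantom(inclusions = list(inclusion(c(50, 30, 7.5), 12),
                              inclusion(c(55, 30, 7.5), 12))),
    "overlap")
  expect_error(material_props(-1, 1457, 0.33), "positive")
  expect_error(inclusion(c(10, 10, 7.5), 6, bubble_fraction = 1), "0, 1")
})
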