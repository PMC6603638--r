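cfg0 <- no_noise(acquisition_config())

test_that("noiseless indentation is linear at the true stiffness and stops at the trigger", {
  for (k in c(0.33, 4.6)) {
    r <- simulate_indentation(k, cfg0, rng_state = 3)
    expect_s3_class(r, "indentation_record")
    expect_length(r$force_trace, length(r$z_trace))
    expect_true(all(diff(r$z_trace) >= 0))
    expect_gte(r$force_trace[r$trigger_index], cfg0$force_trigger)
    expect_identical(r$trigger_index, length(r$force_trace))
    # secant slope over the contact segment equals k to machine precision
    seg <- r$force_trace > 0
    fit <- diff(range(r$force_trace[seg])) / diff(range(r$z_trace[seg]))
    expect_equal(fit, k, tolerance = 1e-12)
    # force monotone non-decreasing after contact
    expect_true(all(diff(r$force_trace[seg]) >= 0))
  }
  expect_error(simulate_indentation(-1, cfg0), "positive")
})

test_that("post-contact travel to the trigger matches trigger/k", {
  r <- simulate_indentation(4.6, cfg0, rng_state = 5)
  contact <- which(r$force_trace > 0)[1]
  travel <- r$z_trace[r$trigger_index] - r$z_trace[contact - 1L]
  dz <- cfg0$indentation_speed / cfg0$force_sample_rate
  # contact and trigger are each located to one sample of travel
  expect_lt(abs(travel - 0.2 / 4.6), 2 * dz)
})

test_that("indentation records are deterministic given the rng state", {
  cfg <- acquisition_config()   # with noise
  a <- simulate_indentation(1, cfg, rng_state = 11)
  b <- simulate_indentation(1, cfg, rng_state = 11)
  expect_identical(a, b)
  c_ <- simulate_indentation(1, cfg, rng_state = 12)
  expect_false(identical(a$force_trace, c_$force_trace))
})

test_that("echo arrival matches the two-way time of flight within one sample", {
  a <- simulate_ascan(phantom(), 50, 30, cfg0)
  t_peak <- (which.max(abs(a$waveform)) - 1) / a$sample_rate
  expect_lt(abs(t_peak - 2 * 15e-3 / 1457), 1 / a$sample_rate)
  # a stiff-matrix (slower-path? no: faster) phantom arrives earlier
  a2 <- simulate_ascan(phantom(matrix_material = tumor_material()), 50, 30, cfg0)
  t2 <- (which.max(abs(a2$waveform)) - 1) / a2$sample_rate
  expect_lt(abs(t2 - 2 * 15e-3 / 1534), 1 / a2$sample_rate)
  expect_lt(t2, t_peak)
})

test_that("echo amplitude drops over inclusions and follows dB attenuation", {
  ph <- small_phantom(diameter = 12, center = c(20, 15, 7.5))
  off <- simulate_ascan(ph, 5, 5, cfg0)
  on <- simulate_ascan(ph, 20, 15, cfg0)
  expect_lt(max(abs(on$waveform)), max(abs(off$waveform)))
  # doubling alpha squares the amplitude ratio A/A0
  peak_for_alpha <- function(alpha) {
    m <- material_props(1.59, 1457, 0.33, attenuation = alpha)
    max(abs(simulate_ascan(phantom(matrix_material = m), 50, 30, cfg0)$waveform))
  }
  a0 <- cfg0$echo_amplitude
  r1 <- peak_for_alpha(1.25) / a0
  r2 <- peak_for_alpha(2.5) / a0
  # sampled peaks carry a common sub-sample carrier-phase factor (< 5e-4)
  expect_equal(r2, r1^2, tolerance = 2e-3)
})

test_that("air bubbles restore the echo toward the inclusion-free amplitude", {
  mk <- function(bf) {
    phantom(length_mm = 40, width_mm = 30,
            inclusions = list(inclusion(c(20, 15, 7.5), 12,
                                        has_air_bubble = bf > 0,
                                        bubble_fraction = bf)))
  }
  ref <- max(abs(simulate_ascan(mk(0), 5, 5, cfg0)$waveform))
  p0 <- max(abs(simulate_ascan(mk(0), 20, 15, cfg0)$waveform))
  p5 <- max(abs(simulate_ascan(mk(0.5), 20, 15, cfg0)$waveform))
  p9 <- max(abs(simulate_ascan(mk(0.9), 20, 15, cfg0)$waveform))
  expect_true(p0 < p5 && p5 < p9 && p9 < ref)
  expect_equal(p5, p0 + 0.5 * (ref - p0), tolerance = 1e-3)
})

test_that("scan datasets are aligned, deterministic and spatially invariant when homogeneous", {
  grid <- cbind(x = c(5, 10, 20, 30, 35), y = c(5, 10, 15, 20, 25))
  cfg <- acquisition_config(seed = 9)
  ds <- simulate_scan(small_phantom(), grid, cfg)
  expect_length(ds$records, 5)
  expect_length(ds$ascans, 5)
  expect_identical(nrow(ds$grid), 5L)
  for (i in 1:5)
    expect_identical(ds$records[[i]]$grid_point, as.numeric(grid[i, ]))
  ds2 <- simulate_scan(small_phantom(), grid, cfg)
  expect_identical(ds, ds2)
  # homogeneous, noiseless: identical post-contact slopes everywhere
  hom <- simulate_scan(phantom(), grid, no_noise(acquisition_config()))
  slopes <- vapply(hom$records, function(r) {
    seg <- r$force_trace > 0
    diff(range(r$force_trace[seg])) / diff(range(r$z_trace[seg]))
  }, numeric(1))
  expect_equal(slopes, rep(0.33, 5), tolerance = 1e-12)
  expect_error(simulate_scan(small_phantom(), cbind(100, 100), cfg), "point 1")
})

test_that("per-point noise substreams are tied to the point, not the scan order", {
  grid <- cbind(x = c(5, 10, 20), y = c(5, 10, 15))
  cfg <- acquisition_config(seed = 9)
  ds <- simulate_scan(small_phantom(), grid, cfg)
  s1 <- nodulecad:::derive_seed(cfg$seed, 2L, 10L)
  rec <- simulate_indentation(local_stiffness(small_phantom(), 10, 10), cfg,
                              rng_state = s1, grid_point = c(10, 10))
  expect_identical(ds$records[[2]], rec)
})
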