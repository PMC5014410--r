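test_that("sequence presets reproduce the protocol table", {
  a <- sequence_preset("a")
  expect_equal(a$fov_mm, 19.2)
  expect_equal(a$matrix, 256)
  expect_equal(a$slice_thickness_mm, 1)
  expect_equal(a$bandwidth_khz, 100.0)
  expect_equal(a$tr_ms, 1600)
  expect_equal(a$te_eff_ms, 20)
  f <- sequence_preset("f")
  expect_equal(f$slice_thickness_mm, 0.5)
  expect_equal(f$fov_mm, 25.6)
  cc <- sequence_preset("c")
  expect_equal(range(cc$te_eff_ms), c(11, 176))
  expect_gt(length(cc$te_eff_ms), 2)
  expect_error(sequence_preset("q"))
})

test_that("simulation is bit-identical under a fixed seed", {
  nz <- noise_model(snr = 20, seed = 11L)
  s1 <- simulate_scan(default_spec, "a", "axial", noise = nz, n_slices = 1)
  s2 <- simulate_scan(default_spec, "a", "axial", noise = nz, n_slices = 1)
  expect_identical(s1$data, s2$data)
  s3 <- simulate_scan(default_spec, "a", "axial",
                      noise = noise_model(20, seed = 12L), n_slices = 1)
  expect_false(identical(s1$data, s3$data))
})

test_that("Rician noise has the expected background statistics", {
  img <- array(0, dim = c(200, 500))       # zero-signal background
  expect_identical(add_rician_noise(img, 0), img)
  out <- add_rician_noise(img, sigma = 2, seed = 5)
  # Rayleigh mean sigma * sqrt(pi/2)
  expect_equal(mean(out), 2 * sqrt(pi / 2), tolerance = 0.02)
  out2 <- add_rician_noise(img, sigma = 2, seed = 5)
  expect_identical(out, out2)
  expect_error(add_rician_noise(img, -1), "sigma")
})

test_that("multi-echo signals decay with the solution T2", {
  me <- simulate_multiecho(default_spec, echoes_ms = c(10, 50), n_slices = 1)
  ctr <- c(128, 128, 1)
  s10 <- me$stacks[[1]]$data[ctr[1], ctr[2], 1]
  s50 <- me$stacks[[2]]$data[ctr[1], ctr[2], 1]
  expect_equal(s50 / s10, exp(-40 / 53.1), tolerance = 1e-10)
  expect_error(simulate_multiecho(default_spec, echoes_ms = c(10, 10)),
               "distinct")
  # noiseless T2 fit recovers the solution T2 exactly
  tm <- fit_t2_map(me)
  expect_equal(median(tm$t2[tm$mask]), 53.1, tolerance = 1e-8)
})

test_that("implanted scaling errors change measured dimensions as implanted", {
  m0 <- measure_dimensions(axial_scan())
  expect_lt(abs(m0$value[m0$direction == "x"] - 12.80), 0.0375)
  expect_lt(abs(m0$value[m0$direction == "y"] - 8.45), 0.0375)

  d <- distortion_model(scale_error_pct = c(2, 0, 0))
  st <- simulate_scan(default_spec, "a", "axial", distortion = d,
                      n_slices = 3)
  m <- measure_dimensions(st)
  expect_equal(m$value[m$direction == "x"], 12.80 * 1.02, tolerance = 0.04 / 13)
  expect_lt(abs(m$value[m$direction == "y"] - 8.45), 0.0375)
})

test_that("swapping the encoding axes flips metadata but not geometry", {
  s1 <- axial_scan()
  s2 <- simulate_scan(default_spec, "a", "axial", encoding_swap = TRUE,
                      n_slices = 3)
  expect_identical(s1$data, s2$data)
  expect_identical(s1$freq_axis, "x"); expect_identical(s1$phase_axis, "y")
  expect_identical(s2$freq_axis, "y"); expect_identical(s2$phase_axis, "x")
  # encoding roles follow the swap in the measurement records
  m2 <- measure_dimensions(s2)
  expect_identical(m2$encoding_role[m2$direction == "y"], "frequency")
})

test_that("a frequency-encoding shift moves the phantom without resizing it", {
  d <- distortion_model(encoding_shift_mm = 0.5)
  st <- simulate_scan(default_spec, "a", "axial", distortion = d,
                      n_slices = 3)
  m <- measure_dimensions(st)
  m0 <- measure_dimensions(axial_scan())
  expect_equal(m$value, m0$value, tolerance = 1e-3)
})

test_that("the bias field modulates intensity multiplicatively", {
  nz <- noise_model(snr = Inf, bias_field = c(0.2, 0, 0, 0, 0))
  st <- simulate_scan(default_spec, "a", "axial", noise = nz, n_slices = 1)
  s0 <- axial_scan()
  sl <- st$data[, , 1]; sl0 <- s0$data[, , 2]
  right <- sl[128, 200] / sl0[128, 200]
  left <- sl[128, 56] / sl0[128, 56]
  expect_gt(right, 1); expect_lt(left, 1)
})

test_that("CT simulation validates resolution and clips warn on small FOV", {
  expect_error(simulate_ct(default_spec, iso_resolution_mm = 0.2),
               "too coarse")
  p <- sequence_preset("a"); p$fov_mm <- 10
  expect_warning(simulate_scan(default_spec, p, "axial", n_slices = 1),
                 "clipped")
})

test_that("the nonlinear field respects its magnitude bound", {
  b <- nonlinear_bump(c(0, 0, 0), 2, c(0.5, 0, 0))
  expect_error(distortion_model(nonlinear = b), "exceeds bound")
  b2 <- nonlinear_bump(c(0, 0, 0), 2, c(0.2, 0, 0))
  expect_silent(distortion_model(nonlinear = b2))
  # b-spline lattice evaluation is smooth and bounded by its controls
  cf <- array(0, dim = c(5, 5, 5, 3)); cf[3, 3, 3, 1] <- 0.25
  nb <- nonlinear_bspline(origin = c(-4, -4, -4), spacing_mm = 2, coef = cf)
  u <- nb$eval(seq(-4, 4, by = 0.5), 0, 0)
  expect_true(all(abs(u$x) <= 0.25 + 1e-12))
  expect_true(all(u$y == 0))
})
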