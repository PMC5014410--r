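px_a <- 19.2 / 256

fixed_slice <- function() cached("regfix",
  simulate_scan(default_spec, "a", "axial", n_slices = 1)$data[, , 1])

test_that("displacement magnitude is the per-pixel Euclidean norm", {
  z <- list(dx = matrix(0, 4, 4), dy = matrix(0, 4, 4))
  expect_true(all(displacement_magnitude(z) == 0))
  c345 <- list(dx = matrix(3, 4, 4), dy = matrix(4, 4, 4))
  expect_true(all(displacement_magnitude(c345) == 5))
  set.seed(2)
  f <- list(dx = matrix(rnorm(36), 6), dy = matrix(rnorm(36), 6))
  expect_equal(displacement_magnitude(f), sqrt(f$dx^2 + f$dy^2))
  # invariant to axis sign conventions
  f2 <- list(dx = -f$dx, dy = f$dy)
  expect_equal(displacement_magnitude(f2), displacement_magnitude(f))
  bad <- list(dx = matrix(NA_real_, 2, 2), dy = matrix(0, 2, 2))
  expect_error(displacement_magnitude(bad), "finite")
})

test_that("rigid registration recovers identity, shifts and rotations", {
  fx <- fixed_slice()
  r0 <- register_rigid(fx, fx, px_a)
  expect_lt(abs(r0$theta_deg), 1e-3)
  expect_lt(abs(r0$tx_mm), 1e-3); expect_lt(abs(r0$ty_mm), 1e-3)

  mv <- simulate_scan(default_spec, "a", "axial",
                      distortion = distortion_model(encoding_shift_mm = 0.5),
                      n_slices = 1)$data[, , 1]
  rs <- register_rigid(mv, fx, px_a)
  expect_lt(abs(abs(rs$tx_mm) - 0.5), 0.05)
  expect_lt(abs(rs$ty_mm), 0.05)

  mr <- apply_rigid(fx, list(theta_deg = 5, tx_mm = 0, ty_mm = 0), px_a)
  rr <- register_rigid(mr, fx, px_a)
  expect_lt(abs(abs(rr$theta_deg) - 5), 0.2)
})

test_that("free-form registration is near-zero on identical images", {
  fx <- fixed_slice()
  f <- suppressWarnings(register_bspline(fx, fx, px_a,
                                         control_spacing_mm = 2))
  m <- displacement_magnitude(f)
  expect_lt(quantile(m, 0.99), 0.02)
  expect_lte(f$residual, f$residual0 + 1e-12)
})

test_that("an implanted smooth bump is recovered at the phantom edge", {
  fx <- fixed_slice()
  b <- nonlinear_bump(center = c(6.4, 0, 0), sigma_mm = 2,
                      amplitude_mm = c(0.3, 0, 0))
  mv <- simulate_scan(default_spec, "a", "axial",
                      distortion = distortion_model(nonlinear = b),
                      n_slices = 1)$data[, , 1]
  f <- suppressWarnings(register_bspline(mv, fx, px_a,
                                         control_spacing_mm = 2,
                                         max_iter = 300))
  m <- displacement_magnitude(f)
  co <- phantomqa:::image_coords_mm(fx, px_a)
  X <- matrix(co$x, 256, 256, byrow = TRUE)
  Y <- matrix(co$y, 256, 256)
  inph <- abs(X) <= 7.5 & abs(Y) <= 5.3
  mm <- m; mm[!inph] <- 0
  pk <- which(mm == max(mm), arr.ind = TRUE)[1, ]
  # peak along the bump's centre line (y = 0) within 2 pixels
  expect_lt(abs(co$y[pk[1]]), 2 * px_a + px_a / 2)
  # recovered magnitude within 30 % of the true local displacement
  u_true <- 0.3 * exp(-((co$x[pk[2]] - 6.4)^2 + co$y[pk[1]]^2) / (2 * 4))
  expect_lt(abs(max(mm) - u_true) / u_true, 0.3)
  expect_lt(f$residual, f$residual0)
})

test_that("uniform expansion yields displacement growing with radius", {
  fx <- fixed_slice()
  mv <- simulate_scan(default_spec, "a", "axial",
                      distortion = distortion_model(c(2, 2, 0)),
                      n_slices = 1)$data[, , 1]
  f <- suppressWarnings(register_bspline(mv, fx, px_a,
                                         control_spacing_mm = 2,
                                         max_iter = 300))
  m <- displacement_magnitude(f)
  co <- phantomqa:::image_coords_mm(fx, px_a)
  X <- matrix(co$x, 256, 256, byrow = TRUE)
  Y <- matrix(co$y, 256, 256)
  rad <- sqrt(X^2 + Y^2)
  sel <- rad < 7
  expect_gt(cor(m[sel], rad[sel]), 0.9)
})

test_that("the full deformation-map workflow runs against a reference", {
  fx <- fixed_slice()
  mv <- simulate_scan(default_spec, "a", "axial",
                      distortion = distortion_model(encoding_shift_mm = 0.3),
                      n_slices = 1)$data[, , 1]
  dm <- suppressWarnings(deformation_map(mv, fx, px_a,
                                         control_spacing_mm = 3,
                                         max_iter = 60))
  expect_true(all(is.finite(dm$magnitude)))
  # rigid stage should have absorbed the bulk shift
  expect_lt(abs(abs(dm$params$tx_mm) - 0.3), 0.05)
  expect_lt(median(dm$magnitude), 0.1)
})

test_that("bicubic resampling preserves constants and approximate shape", {
  img <- matrix(5, 32, 32)
  out <- resample_bicubic(img, 48, 48)
  expect_equal(max(abs(out - 5)), 0, tolerance = 1e-9)
  ramp <- matrix(rep(seq(0, 1, length.out = 64), each = 64), 64)
  up <- resample_bicubic(ramp, 64, 128)
  expect_equal(dim(up), c(64L, 128L))
  expect_true(all(diff(up[32, 10:110]) > -1e-9))
})
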