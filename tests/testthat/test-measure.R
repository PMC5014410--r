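test_that("T2 fitting is exact on noiseless decays and flags degeneracies", {
  # exact two-point log fit at the solution T2
  f2 <- fit_t2_map(list(array(0.8285, c(1, 1)), array(0.3900, c(1, 1))),
                   c(10, 50))
  expect_equal(f2$t2[1, 1], 53.1, tolerance = 0.002)
  # any >= 2 distinct echoes, exact
  te <- c(12, 37, 81, 144)
  imgs <- lapply(te, function(t) array(2.5 * exp(-t / 61), c(2, 3)))
  f <- fit_t2_map(imgs, te)
  expect_equal(max(abs(f$t2 - 61)), 0, tolerance = 1e-9)
  expect_equal(f$s0[1, 1], 2.5, tolerance = 1e-9)
  # constant signal: infinite T2, masked
  fc <- fit_t2_map(list(array(1, c(2, 2)), array(1, c(2, 2))), c(10, 50))
  expect_true(all(!fc$mask))
  expect_true(all(is.na(fc$t2)))
  expect_error(fit_t2_map(imgs, c(10, 10, 20, 30)), "distinct")
})

test_that("noisy T2 estimates stay within 5 % of truth (seeded)", {
  te <- seq(11, 176, by = 11)
  set.seed(42); n <- 500; sig <- 1 / 20           # SNR 20
  stacks <- lapply(exp(-te / 53.1), function(s)
    sqrt((matrix(s, n, 1) + rnorm(n, 0, sig))^2 + rnorm(n, 0, sig)^2))
  f <- fit_t2_map(stacks, te, sigma = sig)
  expect_lt(abs(median(f$t2, na.rm = TRUE) - 53.1) / 53.1, 0.05)
})

test_that("map inversion swaps contrast and is involutive", {
  expect_equal(invert_map(c(0, 1, 2)), c(2, 1, 0))
  expect_equal(invert_map(c(3, 3, 3)), c(0, 0, 0))
  x <- matrix(runif(20), 4)
  x[1, 1] <- 0                      # involutive for zero-background maps
  expect_equal(invert_map(invert_map(x)), x)
  # on multi-echo data the inverted T2 map is compartment-bright
  me <- simulate_multiecho(default_spec, echoes_ms = c(11, 33, 55, 77),
                           n_slices = 1)
  tm <- fit_t2_map(me, noise_floor = 1e-3)
  t2 <- tm$t2; t2[!tm$mask] <- 0                  # plastic/air to zero
  inv <- invert_map(t2)
  gt <- suppressWarnings(rasterize_phantom(default_spec,
                                           me$stacks[[1]]$grid, 2))
  comp <- gt$labels[, , 1] == gt$classes[["compartment_solution"]]
  plast <- gt$labels[, , 1] == gt$classes[["plastic"]]
  expect_lt(median(inv[comp]), median(inv[plast]))   # T2 map: solution high
  expect_gt(median(t2[comp], na.rm = TRUE), 0)       # so inversion darkens it
})

test_that("edge detection is sub-pixel exact and invariant", {
  p <- step_profile(121, 10.25, 110.75)
  e <- edge_positions(p, pixel_mm = 0.075)
  expect_equal(e$left, 10.25, tolerance = 1e-9)
  expect_equal(e$right, 110.75, tolerance = 1e-9)
  expect_equal(e$length_mm, 7.5375, tolerance = 1e-9)
  # symmetric profile gives edges symmetric about the centre
  ps <- step_profile(121, 20.5, 100.5)
  es <- edge_positions(ps)
  expect_equal(es$left + es$right, 20.5 + 100.5, tolerance = 1e-9)
  # invariance to intensity offset and scale
  e2 <- edge_positions(3 * p + 7, pixel_mm = 0.075)
  expect_equal(e2$length_mm, e$length_mm, tolerance = 1e-9)
  # failure modes
  expect_error(edge_positions(rep(0, 50)), "plateau|crossing")
  two <- c(rep(0, 10), rep(1, 10), rep(0, 10), rep(1, 10), rep(0, 10))
  expect_error(edge_positions(two, strict = TRUE), "ambiguous")
  expect_silent(edge_positions(two, strict = FALSE))
})

test_that("dimension measurement is accurate in every plane", {
  for (st in list(axial_scan(), coronal_scan(),
                  cached("sag3", simulate_scan(default_spec, "a", "sagittal",
                                               n_slices = 3)))) {
    m <- measure_dimensions(st)
    for (i in seq_len(nrow(m)))
      expect_lt(abs(m$value[i] - truth_dims[m$direction[i]]), 0.0375)
  }
})

test_that("measurement is invariant to 180-degree image rotation", {
  st <- axial_scan()
  m0 <- measure_dimensions(st)
  rot <- st
  rot$data <- st$data[dim(st$data)[1]:1, dim(st$data)[2]:1, , drop = FALSE]
  m1 <- measure_dimensions(rot)
  expect_equal(m1$value, m0$value, tolerance = 1e-6)
})

test_that("a six-scan set yields 12 dimension records, 4 per direction", {
  recs <- cached("scanset0",
    phantomqa:::scan_set(default_spec, sequence_preset("a"), NULL, NULL,
                         seed = 1, dims_n_slices = 3))
  dims <- recs[recs$kind == "dimension", ]
  expect_equal(nrow(dims), 12)
  expect_equal(as.integer(table(dims$direction)), rep(4L, 3))
  expect_setequal(unique(dims$encoding_role), c("frequency", "phase"))
  # volumes measured on the two axial scans only
  expect_equal(sum(recs$kind == "volume"), 2)
})

test_that("measured dimension grows monotonically with implanted scaling", {
  vals <- vapply(c(-2, 0, 2), function(s) {
    st <- simulate_scan(default_spec, "a", "axial",
                        distortion = distortion_model(c(s, 0, 0)),
                        n_slices = 1)
    m <- measure_dimensions(st)
    m$value[m$direction == "x"]
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})
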