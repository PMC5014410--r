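test_that("scaling and volumetric errors are plain percent deviations", {
  expect_equal(scaling_error(12.80, 12.80), 0)
  expect_equal(scaling_error(13.3722, 12.80), 4.47, tolerance = 1e-4)
  expect_equal(scaling_error(8.0276, 8.45), -4.999, tolerance = 1e-3)
  expect_equal(volumetric_error(153.14, 153.14), 0)
  expect_equal(volumetric_error(181.82, 153.14), 18.73, tolerance = 0.01 / 18)
  expect_equal(volumetric_error(0, 153.14), -100)
  expect_error(scaling_error(1, 0), "> 0")
  expect_error(volumetric_error(1, -5), "> 0")
})

test_that("predicted volumetric error follows the three-axis product", {
  expect_equal(predicted_volumetric_error(0, 0, 0), 0)
  expect_equal(predicted_volumetric_error(1, 1, 1), 3.0301, tolerance = 1e-9)
  expect_equal(predicted_volumetric_error(4.47, 4.82, 4.47), 14.40,
               tolerance = 0.01 / 14.4)
  # symmetric under permutation, strictly increasing in each argument
  expect_equal(predicted_volumetric_error(1, 2, 3),
               predicted_volumetric_error(3, 1, 2))
  expect_gt(predicted_volumetric_error(1.1, 2, 3),
            predicted_volumetric_error(1, 2, 3))
  expect_error(predicted_volumetric_error(-101, 0, 0), "-100")
})

test_that("measured-vs-predicted differences come in both labelled forms", {
  d0 <- measured_vs_predicted_difference(5, 5)
  expect_equal(d0$simple_points, 0); expect_equal(d0$ratio_pct, 0)
  d <- measured_vs_predicted_difference(18.73, 14.40)
  expect_equal(d$simple_points, 4.33, tolerance = 1e-9)
  expect_equal(d$ratio_pct, 100 * (118.73 / 114.40 - 1), tolerance = 1e-9)
  expect_equal(d$ratio_pct, 3.785, tolerance = 1e-3)
  # simple difference is antisymmetric under swapping the arguments
  expect_equal(measured_vs_predicted_difference(3, 7)$simple_points,
               -measured_vs_predicted_difference(7, 3)$simple_points)
})

test_that("summaries use interpolated quantiles per group", {
  s <- summarize_errors(c(1, 2, 3, 4))
  expect_equal(s$median, 2.5)
  expect_equal(s$iqr, unname(diff(quantile(1:4, c(0.25, 0.75), type = 7))))
  s1 <- summarize_errors(7)
  expect_equal(s1$median, 7); expect_equal(s1$iqr, 0)
  g <- summarize_errors(c(1, 2, 10, 20),
                        groups = list(grp = c("a", "a", "b", "b")))
  expect_equal(g$median[g$grp == "b"], 15)
  expect_error(summarize_errors(numeric(0)), "empty")
})

test_that("Mann-Whitney U matches exhaustive pair counting", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_setequal(c(r$U_a, r$U_b), c(0, 9))
  set.seed(7)
  for (i in 1:25) {
    na <- sample(1:8, 1); nb <- sample(1:8, 1)
    a <- sample(1:6, na, replace = TRUE)      # ties likely
    b <- sample(1:6, nb, replace = TRUE)
    r <- mann_whitney_u(a, b)
    expect_equal(r$U_a, brute_force_u(a, b))
    expect_equal(r$U_b, brute_force_u(b, a))
    expect_equal(r$U_a + r$U_b, na * nb)
  }
})

test_that("exact Mann-Whitney p agrees with the reference implementation", {
  set.seed(11)
  for (i in 1:10) {
    a <- rnorm(6); b <- rnorm(7) + 0.5        # continuous: no ties
    r <- mann_whitney_u(a, b)
    w <- suppressWarnings(wilcox.test(a, b, exact = TRUE, correct = TRUE))
    expect_equal(r$method, "exact")
    expect_equal(r$p, w$p.value, tolerance = 1e-12)
  }
  # tie-corrected normal approximation against the reference
  a <- c(1, 2, 2, 3, 5, 5, 6); b <- c(2, 3, 3, 4, 5, 7, 8, 8)
  r <- mann_whitney_u(a, b)
  w <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
  expect_equal(r$p, w$p.value, tolerance = 1e-9)
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("Bland-Altman limits behave as mean +/- 1.96 SD", {
  ba0 <- bland_altman(1:5, 1:5)
  expect_equal(ba0$mean_diff, 0)
  expect_equal(unname(ba0$loa), c(0, 0))
  bac <- bland_altman(1:5 + 2, 1:5)
  expect_equal(bac$mean_diff, 2)
  expect_equal(unname(bac$loa), c(2, 2))
  set.seed(3)
  a <- rnorm(1e4); b <- rnorm(1e4)
  ba <- bland_altman(a, b)
  cover <- mean(ba$differences >= ba$loa[1] & ba$differences <= ba$loa[2])
  expect_equal(cover, 0.95, tolerance = 0.011)
  expect_error(bland_altman(1:3, 1:4), "equal length")
})

test_that("Dice coefficient matches hand counts", {
  a <- matrix(FALSE, 4, 4); b <- a
  a[1:2, 1:2] <- TRUE                # 2x2 square
  b[2:3, 1:2] <- TRUE                # overlapping in 2 pixels
  expect_equal(dice(a, b), 2 * 2 / (4 + 4))
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, !a & FALSE), 0)
  expect_warning(d0 <- dice(a & FALSE, b & FALSE), "empty")
  expect_equal(d0, 1)
  expect_error(dice(matrix(TRUE, 2, 2), matrix(TRUE, 3, 3)), "shape")
})
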