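test_that("record analysis groups errors and applies the volume prediction", {
  recs <- data.frame(
    kind = c(rep("dimension", 6), "volume"),
    direction = c("x", "x", "y", "y", "z", "z", NA),
    encoding_role = c(rep(c("frequency", "phase"), 3), NA),
    value = c(12.928, 12.928, 8.5345, 8.5345, 12.928, 12.928, 170),
    scanner = "S1", stringsAsFactors = FALSE)
  an <- analyze_records(recs, default_spec, group = "scanner")
  expect_equal(an$summary$e_x, 1, tolerance = 1e-9)
  expect_equal(an$summary$e_y, 1, tolerance = 1e-9)
  expect_equal(an$summary$pe_v, predicted_volumetric_error(1, 1, 1),
               tolerance = 1e-9)
  expect_equal(an$summary$e_v, volumetric_error(170, analytic_volume()),
               tolerance = 1e-9)
  expect_false(an$summary$within_bounds)   # 1 % medians sit on the bound
})

test_that("a simulated study is deterministic and flags bad scanners", {
  scanners <- list(
    A = list(distortion = distortion_model(c(4.47, 4.82, 4.47)), snr = 40),
    ok = list(distortion = NULL, snr = 40))
  s1 <- cached("study1", run_study(scanners, default_spec, seed = 7))
  s2 <- run_study(scanners, default_spec, seed = 7)
  expect_identical(s1$summary, s2$summary)
  expect_identical(s1$records, s2$records)

  summ <- s1$summary
  expect_false(summ$within_bounds[summ$group == "A"])
  expect_true(summ$within_bounds[summ$group == "ok"])
  # clean scanner's medians within a half pixel equivalent
  half_px <- 100 * (19.2 / 256 / 2) / 8.45
  expect_true(all(abs(unlist(
    summ[summ$group == "ok", c("e_x", "e_y", "e_z")])) < half_px))
  # scanner A's implanted distortion recovered in the medians
  expect_equal(summ$e_x[summ$group == "A"], 4.47, tolerance = 0.1 / 4.47)
  expect_match(paste(s1$report, collapse = "\n"), "\\| A \\|.*NO")
})

test_that("longitudinal runs label time points and test encoding roles", {
  lg <- run_longitudinal(
    time_points = c("d0", "w1"),
    distortions = list(distortion_model(c(-0.33, -0.5, 0.25)),
                       distortion_model(c(0.1, -0.41, 0.2))),
    spec = default_spec, snr = 40, seed = 3)
  expect_setequal(unique(lg$records$time_point), c("d0", "w1"))
  expect_equal(nrow(lg$summary), 2)
  expect_true(all(c("U_a", "U_b", "p") %in% names(lg$encoding_test)))
  expect_equal(lg$encoding_test$U_a + lg$encoding_test$U_b, 12 * 12)
  expect_error(run_longitudinal(c("d0", "d0"), list(NULL)), "unique")
})

test_that("the workbook reader normalizes CSV sheets and reports schema", {
  dirpath <- withr::local_tempdir()
  between <- data.frame(
    Scanner = c("A", "A", "B"), Sequence = "a",
    Plane = c("axial", "axial", "coronal"),
    Direction = c("x", "y", "x"),
    Encoding = c("frequency", "phase", "frequency"),
    Value = c(13.37, 8.85, 12.81))
  within <- data.frame(
    TimePoint = c("d0", "d0", "d1"), Axis = c("x", "y", NA),
    Type = c("dimension", "dimension", "volume"),
    Measurement = c(12.76, 8.41, 164.4))
  write.csv(between, file.path(dirpath, "between_scanner.csv"),
            row.names = FALSE)
  write.csv(within, file.path(dirpath, "within_scanner.csv"),
            row.names = FALSE)
  tbl <- read_qa_workbook(dirpath)
  expect_equal(nrow(tbl), 6)
  expect_setequal(unique(tbl$sheet), c("between_scanner", "within_scanner"))
  expect_equal(tbl$kind[tbl$sheet == "within_scanner"],
               c("dimension", "dimension", "volume"))
  expect_equal(sum(tbl$kind == "volume"), 1)

  expect_error(read_qa_workbook(file.path(dirpath, "nothere.xlsx")),
               "not found")
  bad <- withr::local_tempdir()
  write.csv(data.frame(foo = 1, bar = 2), file.path(bad, "sheet1.csv"),
            row.names = FALSE)
  expect_error(read_qa_workbook(bad), "unrecognized workbook layout.*sheet1")
})

test_that("the replication harness recomputes summary statistics", {
  # synthetic longitudinal table with known statistics
  set.seed(5)
  n <- 24
  freq <- round(rnorm(n, 0.12, 0.3), 3)
  phas <- round(rnorm(n, -0.63, 0.4), 3)
  vols <- round(153.14 * (1 + rnorm(10, 0.073, 0.004)), 3)
  tbl <- rbind(
    data.frame(sheet = "within", scanner = NA, sequence = "a",
               time_point = rep(c("d0", "d1"), n)[seq_len(2 * n)],
               plane = "axial",
               direction = c(rep("x", n), rep("y", n)),
               encoding_role = c(rep("frequency", n), rep("phase", n)),
               kind = "dimension",
               value = c(12.80 * (1 + freq / 100), 8.45 * (1 + phas / 100))),
    data.frame(sheet = "within", scanner = NA, sequence = "a",
               time_point = "d0", plane = "axial", direction = NA,
               encoding_role = NA, kind = "volume", value = vols))
  rep <- replicate_results(tbl, default_spec)
  vol_err <- volumetric_error(vols, analytic_volume())
  expect_equal(rep$within_volume$median, median(vol_err), tolerance = 1e-9)
  expect_equal(rep$within_volume$iqr,
               unname(diff(quantile(vol_err, c(0.25, 0.75)))),
               tolerance = 1e-9)
  expect_equal(rep$encoding_test$U_a + rep$encoding_test$U_b, n * n)
  comp <- rep$comparison
  expect_true(all(c("quantity", "reference", "computed", "delta") %in%
                    names(comp)))
  expect_false(is.na(comp$computed[comp$quantity ==
                                     "within_scanner_e_v_median"]))
})
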