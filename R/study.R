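#' Compute per-record errors and per-group summaries from measurements
#'
#' Converts raw measurement records (dimensions in mm, volumes in mm^3) to
#' percent errors against the phantom ground truth and summarizes them:
#' per-direction scaling-error medians, the volumetric-error median, the
#' predicted volumetric error from the direction medians, and both forms of
#' the measured-versus-predicted difference.
#'
#' @param records data.frame with columns `kind` (`"dimension"`/`"volume"`),
#'   `direction` (`"x"/"y"/"z"` for dimensions), `encoding_role`, `value`,
#'   and optionally a grouping column.
#' @param spec the [phantom_spec()] providing ground truth.
#' @param group name of the grouping column (e.g. `"scanner"` or
#'   `"time_point"`); `NULL` treats all records as one group.
#' @param scaling_bound_pct acceptance bound on the per-direction scaling
#'   error medians (clinical guidance suggests +/- 1 %).
#' @return List with `errors` (per-record percent errors) and `summary`
#'   (one row per group).
#' @export
analyze_records <- function(records, spec = phantom_spec(), group = NULL,
                            scaling_bound_pct = 1.0) {
  stopifnot(is.data.frame(records), all(c("kind", "value") %in%
                                          names(records)))
  truth_dim <- c(x = spec$interior_x, y = spec$interior_y,
                 z = spec$interior_z)
  truth_vol <- frustum_volume(spec$frustum_r_top, spec$frustum_r_bottom,
                              spec$frustum_height)
  err <- records
  err$error_pct <- NA_real_
  isd <- err$kind == "dimension"
  err$error_pct[isd] <- scaling_error(err$value[isd],
                                      truth_dim[err$direction[isd]])
  err$error_pct[!isd] <- volumetric_error(err$value[!isd], truth_vol)

  g <- if (is.null(group)) rep("all", nrow(err)) else err[[group]]
  summ <- do.call(rbind, lapply(split(seq_len(nrow(err)), g), function(idx) {
    e <- err[idx, ]
    med_dir <- vapply(c("x", "y", "z"), function(d) {
      v <- e$error_pct[e$kind == "dimension" & e$direction == d]
      if (length(v)) stats::median(v) else NA_real_
    }, numeric(1))
    ev <- e$error_pct[e$kind == "volume"]
    e_v <- if (length(ev)) stats::median(ev) else NA_real_
    pe_v <- if (anyNA(med_dir)) NA_real_ else
      predicted_volumetric_error(med_dir[1], med_dir[2], med_dir[3])
    dd <- if (is.na(e_v) || is.na(pe_v)) list(simple_points = NA_real_,
                                              ratio_pct = NA_real_)
      else measured_vs_predicted_difference(e_v, pe_v)
    data.frame(group = as.character(e[[if (is.null(group)) 1 else group]][1]),
               e_x = med_dir[1], e_y = med_dir[2], e_z = med_dir[3],
               e_v = e_v, pe_v = pe_v,
               diff_points = dd$simple_points, diff_ratio_pct = dd$ratio_pct,
               within_bounds = all(abs(med_dir) <= scaling_bound_pct),
               row.names = NULL)
  }))
  if (is.null(group)) summ$group <- "all"
  rownames(summ) <- NULL
  list(errors = err, summary = summ)
}

# One complete 6-scan set (3 planes x swapped encoding), measured.
scan_set <- function(spec, preset, distortion, noise, seed,
                     dims_n_slices = 3, scan_prefix = "scan") {
  if (is.character(preset)) preset <- sequence_preset(preset)
  cavity_z <- 2 * (max(spec$frustum_r_top, spec$frustum_r_bottom) +
                     spec$compartment_wall)
  n_ax <- ceiling((cavity_z + 2) / preset$slice_thickness_mm) + 2L
  n_ax <- n_ax + (n_ax %% 2L == 0L)       # slice positioned through the middle
  recs <- list(); i <- 0L
  for (plane in c("axial", "coronal", "sagittal")) for (swap in c(FALSE, TRUE)) {
    i <- i + 1L
    ns <- if (plane == "axial") n_ax else dims_n_slices
    nz <- if (is.null(noise)) NULL else
      noise_model(noise$snr, noise$bias_field, seed + i)
    st <- simulate_scan(spec, preset, plane, encoding_swap = swap,
                        distortion = distortion, noise = nz,
                        n_slices = ns)
    id <- sprintf("%s_%s_%s", scan_prefix, plane,
                  if (swap) "swap" else "std")
    recs[[length(recs) + 1L]] <- measure_dimensions(st, scan_id = id)
    if (plane == "axial")
      recs[[length(recs) + 1L]] <- measure_volume(st, scan_id = id)
  }
  do.call(rbind, recs)
}

#' Run a simulated between-scanner QA study
#'
#' For each configured scanner, simulates the full six-scan protocol (three
#' orthogonal planes, each repeated with swapped frequency/phase encoding),
#' measures the twelve internal dimensions (four per direction) and the
#' compartment volume on the axial scans, and summarizes per-scanner scaling
#' and volumetric errors with the prediction implied by linear scaling.
#' Deterministic for a fixed seed.
#'
#' @param scanners named list; each element a list with elements
#'   `distortion` (a [distortion_model()], optional) and `snr`
#'   (optional, default noiseless).
#' @param spec the [phantom_spec()].
#' @param preset sequence preset (letter or object) used for every scanner.
#' @param seed integer master seed; per-scan seeds are derived from it.
#' @param scaling_bound_pct report bound for per-direction medians.
#' @return An object of class `qa_study`: `records`, `errors`, `summary`
#'   and a markdown `report`.
#' @export
run_study <- function(scanners, spec = phantom_spec(), preset = "a",
                      seed = 1L, scaling_bound_pct = 1.0) {
  stopifnot(is.list(scanners), length(names(scanners)) == length(scanners))
  all_rec <- list()
  for (i in seq_along(scanners)) {
    sc <- scanners[[i]]
    nz <- if (!is.null(sc$snr) && is.finite(sc$snr))
      noise_model(sc$snr, sc$bias_field, seed) else NULL
    r <- scan_set(spec, preset, sc$distortion, nz,
                  seed = seed * 1000L + i * 10L,
                  scan_prefix = names(scanners)[i])
    r$scanner <- names(scanners)[i]
    all_rec[[i]] <- r
  }
  records <- do.call(rbind, all_rec)
  an <- analyze_records(records, spec, group = "scanner",
                        scaling_bound_pct = scaling_bound_pct)
  out <- list(records = records, errors = an$errors, summary = an$summary,
              scaling_bound_pct = scaling_bound_pct,
              report = format_qa_report(an$summary, scaling_bound_pct))
  class(out) <- "qa_study"
  out
}

#' Run a simulated longitudinal (within-scanner) assessment
#'
#' One six-scan set per time point (labels like `d0, d1, ..., w1, ..., m6`:
#' daily, weekly and monthly intervals after gradient calibration), with a
#' per-time-point distortion model describing the scanner's drift. Adds the
#' frequency-versus-phase encoding comparison (Mann-Whitney U over all
#' dimension scaling errors) performed on longitudinal data.
#'
#' @param time_points character vector of unique time-point labels.
#' @param distortions list (one [distortion_model()] per time point,
#'   recycled if length 1) or a function `f(index)` returning one.
#' @inheritParams run_study
#' @param snr signal-to-noise ratio applied to every scan (`Inf` = none).
#' @return List with `records`, `errors`, `summary` (per time point) and
#'   `encoding_test` (the U test frequency vs phase).
#' @export
run_longitudinal <- function(time_points, distortions,
                             spec = phantom_spec(), preset = "a",
                             snr = Inf, seed = 1L) {
  if (anyDuplicated(time_points))
    stop("time-point labels must be unique", call. = FALSE)
  get_dist <- if (is.function(distortions)) distortions
    else function(i) distortions[[min(i, length(distortions))]]
  all_rec <- list()
  for (i in seq_along(time_points)) {
    nz <- if (is.finite(snr)) noise_model(snr, seed = seed) else NULL
    r <- scan_set(spec, preset, get_dist(i), nz,
                  seed = seed * 1000L + i * 10L,
                  scan_prefix = time_points[i])
    r$time_point <- time_points[i]
    all_rec[[i]] <- r
  }
  records <- do.call(rbind, all_rec)
  an <- analyze_records(records, spec, group = "time_point")
  dim_err <- an$errors[an$errors$kind == "dimension", ]
  enc <- mann_whitney_u(dim_err$error_pct[dim_err$encoding_role == "frequency"],
                        dim_err$error_pct[dim_err$encoding_role == "phase"])
  list(records = records, errors = an$errors, summary = an$summary,
       encoding_test = enc)
}

format_qa_report <- function(summary, bound = 1.0) {
  lines <- c("# Phantom QA report",
             sprintf("Scaling-error acceptance bound: +/- %.2f %%", bound), "")
  lines <- c(lines,
    "| group | e_x % | e_y % | e_z % | e_V % | pred e_V % | diff (pts) | within bounds |",
    "|---|---|---|---|---|---|---|---|")
  for (i in seq_len(nrow(summary))) {
    s <- summary[i, ]
    lines <- c(lines, sprintf(
      "| %s | %.2f | %.2f | %.2f | %.2f | %.2f | %.2f | %s |",
      s$group, s$e_x, s$e_y, s$e_z, s$e_v, s$pe_v, s$diff_points,
      if (isTRUE(s$within_bounds)) "yes" else "NO"))
  }
  lines
}

#' @export
print.qa_study <- function(x, ...) {
  cat(paste(x$report, collapse = "\n"), "\n")
  invisible(x)
}
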