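#' Simulate a multi-slice T2-weighted scan of the phantom
#'
#' Produces a magnitude image stack with the solution compartments bright
#' (signal proportional to `exp(-TE_eff / T2)` with T2 = 53.1 ms for the
#' doped solution, zero for plastic, tape and air), geometry warped by the
#' distortion model before sampling, partial volume from analytic per-voxel
#' occupancy, an optional multiplicative polynomial bias field,
#' and Rician noise. The signal model is a deliberate two-tissue T2-weighted
#' idealization: no Bloch simulation, echo-train blurring or k-space effects.
#'
#' @param spec a [phantom_spec()].
#' @param preset a [sequence_preset()] (or its letter name).
#' @param plane `"axial"`, `"coronal"` or `"sagittal"`.
#' @param encoding_swap logical; swap the frequency and phase encoding axes
#'   (metadata and encoding-shift direction only: the noiseless geometry is
#'   unchanged because distortion acts in phantom axes).
#' @param distortion a [distortion_model()] or `NULL` (identity).
#' @param noise a [noise_model()] or `NULL` (noiseless, no bias field).
#' @param n_slices number of slices; default covers the phantom plus margin.
#'   A small number (e.g. 3) centred on the phantom is enough for dimension
#'   measurements and much faster.
#' @param te_eff_ms override the preset's effective echo time (required for
#'   multi-echo presets, where [simulate_multiecho()] is the natural entry).
#' @return An object of class `mri_stack`: `data` (rows x cols x slices),
#'   the `grid`, plane, frequency/phase axis labels (phantom axis names), the
#'   effective TE and full provenance.
#' @export
simulate_scan <- function(spec, preset = sequence_preset("a"),
                          plane = c("axial", "coronal", "sagittal"),
                          encoding_swap = FALSE,
                          distortion = NULL, noise = NULL,
                          n_slices = NULL, te_eff_ms = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.character(preset)) preset <- sequence_preset(preset)
  stopifnot(inherits(preset, "sequence_preset"))
  plane <- match.arg(plane)
  if (is.null(te_eff_ms)) te_eff_ms <- preset$te_eff_ms
  if (length(te_eff_ms) != 1)
    stop("preset \"", preset$name, "\" has an echo-time list; give a scalar ",
         "te_eff_ms or use simulate_multiecho()", call. = FALSE)

  axes <- plane_axes(plane)
  px <- preset$fov_mm / preset$matrix
  if (is.null(n_slices)) {
    ext <- phantom_outer_extent(spec)[axes[["slice"]]]
    n_slices <- ceiling(ext / preset$slice_thickness_mm) + 2L
    n_slices <- n_slices + (n_slices %% 2L == 0L)   # central slice at z = 0
  }
  grid <- grid_spec(preset$matrix, preset$matrix, n_slices,
                    pixel_dx = px, pixel_dy = px,
                    slice_thickness = preset$slice_thickness_mm,
                    plane = plane)

  # in-plane encoding roles: frequency along columns unless swapped
  freq_axis  <- unname(if (encoding_swap) axes[["row"]] else axes[["col"]])
  phase_axis <- unname(if (encoding_swap) axes[["col"]] else axes[["row"]])
  shift_mm <- if (is.null(distortion)) 0 else distortion$encoding_shift_mm
  warp <- make_warp(distortion, shift_axis = freq_axis, shift_mm = shift_mm)

  # in-plane FOV check (a deliberately short slice stack is not clipping)
  co <- grid_coords(grid)
  ext <- phantom_outer_extent(spec)
  clipped <- diff(range(co$col)) + px < ext[axes[["col"]]] - 1e-9 ||
    diff(range(co$row)) + px < ext[axes[["row"]]] - 1e-9
  if (clipped)
    warning("phantom clipped by the field of view", call. = FALSE)

  # analytic partial-volume occupancy at warped coordinates; voxel
  # footprints scale with the implanted per-axis scale factors
  w_img <- c(col = grid$pixel_dx, row = grid$pixel_dy,
             slice = grid$slice_thickness)
  w_ph <- numeric(3); names(w_ph) <- c("x", "y", "z")
  w_ph[axes] <- w_img[names(axes)]
  sc <- if (is.null(distortion)) c(1, 1, 1) else
    1 + distortion$scale_error_pct / 100
  w_true <- w_ph / sc

  nr <- grid$matrix_rows; nc <- grid$matrix_cols
  colv <- rep(co$col, each = nr)
  rowv <- rep(co$row, times = nc)
  occ <- array(0, dim = c(nr, nc, grid$n_slices))
  for (k in seq_len(grid$n_slices)) {
    p <- list(col = colv, row = rowv,
              slice = rep_len(co$slice[k], length(colv)))
    ph <- list(x = p[[which(axes == "x")]],
               y = p[[which(axes == "y")]],
               z = p[[which(axes == "z")]])
    w <- warp(ph$x, ph$y, ph$z)
    occ[, , k] <- solution_occupancy(spec, w$x, w$y, w$z,
                                     w_true[["x"]], w_true[["y"]],
                                     w_true[["z"]])$solution
  }
  plateau <- exp(-te_eff_ms / T2_SOLUTION_MS)
  img <- occ * plateau

  if (!is.null(noise)) {
    stopifnot(inherits(noise, "noise_model"))
    if (!is.null(noise$bias_field)) {
      u <- co$col / max(abs(co$col)); v <- co$row / max(abs(co$row))
      b <- noise$bias_field
      B <- 1 + outer(v, u, function(vv, uu)
        b[1] * uu + b[2] * vv + b[3] * uu^2 + b[4] * uu * vv + b[5] * vv^2)
      img <- img * as.vector(B)        # recycled over slices
    }
    if (is.finite(noise$snr))
      img <- add_rician_noise(img, sigma = plateau / noise$snr,
                              seed = noise$seed)
  }

  structure(list(data = img, grid = grid, plane = plane,
                 freq_axis = freq_axis, phase_axis = phase_axis,
                 te_eff_ms = te_eff_ms, preset_name = preset$name,
                 clipped = clipped,
                 provenance = list(spec = spec, preset = preset,
                                   distortion = distortion, noise = noise,
                                   encoding_swap = encoding_swap)),
            class = "mri_stack")
}

#' @export
print.mri_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("mri_stack \"%s\": %d x %d x %d, %s plane, TE %g ms, freq=%s phase=%s\n",
              x$preset_name, d[1], d[2], d[3], x$plane, x$te_eff_ms,
              x$freq_axis, x$phase_axis))
  invisible(x)
}

#' Simulate a multi-echo (MSME) acquisition
#'
#' One stack per echo time with per-voxel signal
#' `S(TE) = S0 * exp(-TE / T2(class))` plus Rician noise; the geometry is
#' rasterized once and shared across echoes so the echoes differ only in
#' decay and noise realization.
#'
#' @inheritParams simulate_scan
#' @param echoes_ms numeric vector of at least two distinct echo times (ms).
#' @return An object of class `multiecho_stack`: list of `mri_stack`s plus
#'   the echo-time vector.
#' @export
simulate_multiecho <- function(spec, echoes_ms = seq(11, 176, by = 11),
                               preset = sequence_preset("c"),
                               plane = "axial", encoding_swap = FALSE,
                               distortion = NULL, noise = NULL,
                               n_slices = NULL) {
  if (is.character(preset)) preset <- sequence_preset(preset)
  if (length(echoes_ms) < 2 || anyDuplicated(echoes_ms))
    stop("echoes_ms must contain at least two distinct echo times",
         call. = FALSE)
  base <- simulate_scan(spec, preset, plane, encoding_swap, distortion,
                        noise = NULL, n_slices = n_slices,
                        te_eff_ms = echoes_ms[1])
  occ <- base$data / exp(-echoes_ms[1] / T2_SOLUTION_MS)   # recover occupancy
  stacks <- vector("list", length(echoes_ms))
  for (i in seq_along(echoes_ms)) {
    st <- base
    st$te_eff_ms <- echoes_ms[i]
    st$data <- occ * exp(-echoes_ms[i] / T2_SOLUTION_MS)
    if (!is.null(noise) && is.finite(noise$snr))
      st$data <- add_rician_noise(st$data, sigma = 1 / noise$snr,
                                  seed = noise$seed + i - 1L)
    stacks[[i]] <- st
  }
  structure(list(stacks = stacks, echoes_ms = echoes_ms),
            class = "multiecho_stack")
}

#' Add Rician noise to a magnitude image
#'
#' `out = sqrt((I + n1)^2 + n2^2)` with `n1, n2 ~ Normal(0, sigma)`, the
#' standard noise model of single-coil MR magnitude data: Gaussian at high
#' SNR, Rayleigh in zero-signal background (mean `sigma * sqrt(pi/2)`).
#'
#' @param image numeric array or matrix.
#' @param sigma noise standard deviation (same units as `image`); 0 returns
#'   the input unchanged.
#' @param seed optional integer seed; the caller's RNG state is preserved.
#' @return Array of the same shape.
#' @export
add_rician_noise <- function(image, sigma, seed = NULL) {
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (sigma == 0) return(image)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  n <- length(image)
  out <- sqrt((image + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
  array(out, dim = dim(image))
}

#' Simulate a high-resolution CT-like volume of the empty phantom
#'
#' Plastic (and tape) are bright, air-filled spaces dark, emulating the
#' reference CT used to calibrate the ground-truth threshold. The volume is
#' stored on an isotropic grid in phantom axes (x, y, z) with coordinate
#' vectors attached.
#'
#' @param spec a [phantom_spec()].
#' @param iso_resolution_mm isotropic voxel size; must be <= 0.1 mm.
#' @param margin_mm air margin around the phantom.
#' @param plastic_value intensity assigned to solid material.
#' @param noise_sd optional additive Gaussian noise SD.
#' @param seed RNG seed for the noise.
#' @return An object of class `ct_volume`: `data` (x fastest), `res`, and
#'   coordinate vectors `x`, `y`, `z` (mm).
#' @export
simulate_ct <- function(spec, iso_resolution_mm = 0.0345, margin_mm = 0.5,
                        plastic_value = 1000, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (iso_resolution_mm > 0.1)
    stop("CT resolution too coarse: need <= 0.1 mm", call. = FALSE)
  ext <- phantom_outer_extent(spec) + 2 * margin_mm
  res <- iso_resolution_mm
  n <- ceiling(ext / res)
  cv <- lapply(seq_along(n), function(a) (seq_len(n[a]) - (n[a] + 1) / 2) * res)
  names(cv) <- c("x", "y", "z")
  dat <- array(0, dim = n)
  xg <- rep(cv$x, times = n[2])
  yg <- rep(cv$y, each = n[1])
  for (k in seq_len(n[3])) {
    dat[, , k] <- plastic_value *
      solid_occupancy(spec, xg, yg, cv$z[k], res, res, res)
  }
  if (noise_sd > 0)
    dat <- add_gaussian_noise(dat, noise_sd, seed)
  structure(list(data = dat, res = res, x = cv$x, y = cv$y, z = cv$z),
            class = "ct_volume")
}

add_gaussian_noise <- function(x, sd, seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  x + array(rnorm(length(x), 0, sd), dim = dim(x))
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("ct_volume: %d x %d x %d at %.4g mm isotropic\n",
              d[1], d[2], d[3], x$res))
  invisible(x)
}

#' Write a scan with its ground-truth provenance sidecar
#'
#' Writes the stack as NIfTI-1 plus a YAML sidecar recording the full
#' simulation provenance (phantom geometry, preset, plane, encoding,
#' implanted distortion and noise model), so simulated datasets remain
#' self-describing.
#'
#' @param stack an `mri_stack`.
#' @param path output path without extension; `.nii.gz` and `.yaml` are
#'   appended.
#' @return The NIfTI path, invisibly.
#' @export
write_scan <- function(stack, path) {
  stopifnot(inherits(stack, "mri_stack"))
  nii <- paste0(path, ".nii.gz")
  write_volume_nifti(stack, nii)
  pv <- stack$provenance
  side <- list(
    preset = stack$preset_name, plane = stack$plane,
    te_eff_ms = stack$te_eff_ms,
    frequency_axis = stack$freq_axis, phase_axis = stack$phase_axis,
    encoding_swap = isTRUE(pv$encoding_swap),
    phantom = if (!is.null(pv$spec)) unclass(pv$spec),
    distortion = if (!is.null(pv$distortion)) list(
      scale_error_pct = pv$distortion$scale_error_pct,
      encoding_shift_mm = pv$distortion$encoding_shift_mm,
      nonlinear = !is.null(pv$distortion$nonlinear)),
    noise = if (!is.null(pv$noise)) list(
      snr = pv$noise$snr, seed = pv$noise$seed,
      bias_field = pv$noise$bias_field))
  yaml::write_yaml(side, paste0(path, ".yaml"))
  invisible(nii)
}
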