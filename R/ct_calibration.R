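# Separable 3D Gaussian smoothing of a ct_volume via sparse band matrices.
gaussian_smooth_ct <- function(ct, fwhm_mm) {
  stopifnot(inherits(ct, "ct_volume"))
  sigma_v <- (fwhm_mm / (2 * sqrt(2 * log(2)))) / ct$res
  r <- max(1L, ceiling(4 * sigma_v))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_v^2))
  k <- k / sum(k)
  d <- dim(ct$data)
  band <- function(n) Matrix::bandSparse(n, n, k = seq(-r, r),
    diagonals = lapply(k, rep, n), symmetric = FALSE)
  v <- ct$data
  K1 <- band(d[1])
  v <- array(as.matrix(K1 %*% matrix(v, d[1], d[2] * d[3])), d)
  K2t <- Matrix::t(band(d[2]))
  for (kk in seq_len(d[3])) v[, , kk] <- as.matrix(v[, , kk] %*% K2t)
  K3t <- Matrix::t(band(d[3]))
  v <- array(as.matrix(matrix(v, d[1] * d[2], d[3]) %*% K3t), d)
  out <- ct
  out$data <- v
  out
}

# Interior extent along a 1D profile of a bright-walled cavity: the distance
# between the inner surface of the first wall and the inner surface of the
# last wall, located as interpolated threshold crossings.
interior_extent <- function(profile, coords, threshold) {
  above <- profile >= threshold
  n <- length(profile)
  di <- diff(above)
  ups <- which(di == 1)      # crossing between i and i+1, going up
  downs <- which(di == -1)
  if (length(ups) < 2 || length(downs) < 2)
    stop("calibration failed: profile lacks two wall crossings",
         call. = FALSE)
  cross_pos <- function(i) {
    f <- (threshold - profile[i]) / (profile[i + 1] - profile[i])
    coords[i] + f * (coords[i + 1] - coords[i])
  }
  left_inner <- cross_pos(downs[1])       # first descent: inner left wall
  right_inner <- cross_pos(ups[length(ups)])  # last ascent: inner right wall
  if (right_inner <= left_inner)
    stop("calibration failed: degenerate profile", call. = FALSE)
  right_inner - left_inner
}

#' Calibrate a CT threshold against caliper dimensions
#'
#' Reproduces the ground-truth procedure: the CT volume is smoothed with a
#' Gaussian kernel (default FWHM 81.2 um), then a single intensity threshold
#' is found such that the binarized phantom mask has exactly the
#' caliper-measured internal dimensions (the sum of the three interior
#' extents matches the sum of the calipers; the per-axis residuals are
#' reported). Interior extents are measured with sub-voxel interpolation on
#' profile lines placed at `line_offset_frac` of each dimension from the
#' phantom centre, clear of the central compartment and tape.
#'
#' @param ct a `ct_volume` from [simulate_ct()] (or compatible).
#' @param caliper_dims length-3 numeric, true internal x/y/z dimensions (mm).
#' @param fwhm_mm Gaussian smoothing kernel FWHM (mm).
#' @param line_offset_frac lateral offset of measurement lines as a fraction
#'   of the corresponding caliper dimension.
#' @return List with `threshold`, `dims_mm` (measured at the calibrated
#'   threshold), `residual_mm`, the `smoothed` volume and the binary air
#'   `mask` (`TRUE` where below threshold).
#' @export
calibrate_ct_threshold <- function(ct, caliper_dims,
                                   fwhm_mm = 0.0812,
                                   line_offset_frac = 0.333) {
  stopifnot(inherits(ct, "ct_volume"), length(caliper_dims) == 3)
  sm <- gaussian_smooth_ct(ct, fwhm_mm)
  nearest <- function(coords, value) which.min(abs(coords - value))
  i_x0 <- nearest(sm$x, 0); i_y0 <- nearest(sm$y, 0)
  i_z0 <- nearest(sm$z, 0)
  i_zoff <- nearest(sm$z, line_offset_frac * caliper_dims[3])
  i_xoff <- nearest(sm$x, line_offset_frac * caliper_dims[1])

  dims_at <- function(thr) c(
    interior_extent(sm$data[, i_y0, i_zoff], sm$x, thr),
    interior_extent(sm$data[i_xoff, , i_z0], sm$y, thr),
    interior_extent(sm$data[i_xoff, i_y0, ], sm$z, thr))

  rng <- range(sm$data)
  if (diff(rng) <= 0)
    stop("calibration failed: uniform-intensity volume", call. = FALSE)
  lo <- rng[1] + 0.05 * diff(rng); hi <- rng[1] + 0.95 * diff(rng)
  g <- function(thr) sum(dims_at(thr)) - sum(caliper_dims)
  glo <- tryCatch(g(lo), error = function(e) e)
  ghi <- tryCatch(g(hi), error = function(e) e)
  if (inherits(glo, "error") || inherits(ghi, "error"))
    stop("calibration failed: dimensions not measurable across the ",
         "threshold range", call. = FALSE)
  if (glo * ghi > 0)
    stop("calibration failed: no threshold reproduces the caliper ",
         "dimensions", call. = FALSE)
  thr <- stats::uniroot(g, c(lo, hi), tol = 1e-6 * diff(rng))$root
  dims <- dims_at(thr)
  list(threshold = thr, dims_mm = dims,
       residual_mm = dims - caliper_dims,
       smoothed = sm, mask = sm$data < thr)
}

#' Compartment volume from a calibrated CT volume
#'
#' Counts air voxels (below the calibrated threshold) belonging, slice by
#' slice perpendicular to the frustum axis (y), to the connected component
#' containing the compartment axis at the volume centre; slices where the
#' centre is solid contribute nothing.
#'
#' @param smoothed the smoothed `ct_volume` (from
#'   [calibrate_ct_threshold()]`$smoothed`).
#' @param threshold the calibrated threshold.
#' @return Volume in mm^3.
#' @export
ct_compartment_volume <- function(smoothed, threshold) {
  stopifnot(inherits(smoothed, "ct_volume"))
  d <- dim(smoothed$data)
  i_x0 <- which.min(abs(smoothed$x)); i_z0 <- which.min(abs(smoothed$z))
  nvox <- 0
  for (k in seq_len(d[2])) {
    m <- smoothed$data[, k, ] < threshold
    if (!m[i_x0, i_z0]) next
    bw <- EBImage::bwlabel(matrix(as.numeric(m), d[1], d[3]))
    lab <- bw[i_x0, i_z0]
    # exterior air touches the slice border; the enclosed compartment never does
    if (any(bw[c(1, d[1]), ] == lab) || any(bw[, c(1, d[3])] == lab)) next
    nvox <- nvox + sum(bw == lab)
  }
  nvox * smoothed$res^3
}
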