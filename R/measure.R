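#' Per-voxel T2 mapping from a multi-echo stack
#'
#' Log-linear least-squares fit of `ln S` against TE per voxel:
#' `S(TE) = S0 exp(-TE / T2)`, exact on noiseless exponentials for any two
#' or more distinct echoes. Each voxel's echo train is truncated at the
#' first sample at or below the noise floor (later echoes of a decaying
#' signal sink into the Rician noise floor and would bias the fit); a voxel
#' needs at least two usable echoes, otherwise it is masked, as are voxels
#' with non-decaying signal (slope >= 0, nominally infinite T2). When the
#' noise standard deviation `sigma` is known, the Rician power correction
#' `S_c = sqrt(max(S^2 - 2 sigma^2, 0))` is applied before the log and the
#' floor defaults to `2 sigma`.
#'
#' @param echo_stack a `multiecho_stack` from [simulate_multiecho()], or a
#'   list of numeric arrays of identical shape (one per echo).
#' @param te_ms echo times (ms); taken from the stack when omitted.
#' @param noise_floor absolute signal threshold at or below which a voxel's
#'   echo train is truncated; default `0` keeps all positive samples.
#' @param sigma optional noise standard deviation for Rician bias
#'   correction.
#' @return List with `t2` (ms, `NA` where masked), `s0`, and logical `mask`
#'   of valid voxels.
#' @export
fit_t2_map <- function(echo_stack, te_ms = NULL, noise_floor = 0,
                       sigma = NULL) {
  if (inherits(echo_stack, "multiecho_stack")) {
    if (is.null(te_ms)) te_ms <- echo_stack$echoes_ms
    imgs <- lapply(echo_stack$stacks, `[[`, "data")
  } else imgs <- echo_stack
  if (is.null(te_ms) || length(te_ms) < 2 || anyDuplicated(te_ms))
    stop("need >= 2 distinct echo times", call. = FALSE)
  stopifnot(length(imgs) == length(te_ms))
  dims <- dim(imgs[[1]])
  ord <- order(te_ms)
  te <- te_ms[ord]
  S <- do.call(cbind, lapply(imgs[ord], as.vector))   # voxels x echoes

  floor_eff <- max(noise_floor, if (is.null(sigma)) 0 else 2 * sigma)
  W <- (S > max(floor_eff, 0)) * 1
  for (j in seq_len(ncol(W))[-1])                     # truncate at first drop
    W[, j] <- W[, j] * W[, j - 1]
  if (!is.null(sigma)) S <- sqrt(pmax(S^2 - 2 * sigma^2, 0))
  L <- log(pmax(S, .Machine$double.xmin)) * W

  n_use <- rowSums(W)
  sw_t  <- as.vector(W %*% te)
  sw_t2 <- as.vector(W %*% te^2)
  sw_l  <- rowSums(L)
  sw_tl <- as.vector(L %*% te)
  denom <- sw_t2 - sw_t^2 / pmax(n_use, 1)
  slope <- (sw_tl - sw_t * sw_l / pmax(n_use, 1)) / denom
  inter <- (sw_l - slope * sw_t) / pmax(n_use, 1)

  valid <- n_use >= 2 & denom > 0 & is.finite(slope) & slope < 0
  t2 <- ifelse(valid, -1 / slope, NA_real_)
  s0 <- ifelse(valid, exp(inter), NA_real_)
  list(t2 = array(t2, dims), s0 = array(s0, dims),
       mask = array(valid, dims))
}

#' Invert an intensity map
#'
#' `I' = max(I) - I` over finite values, so bright and dark regions swap:
#' used to give T2 maps the same phantom-bright contrast as T2-weighted
#' images. Involutive up to the mask: `invert(invert(I)) = I`.
#'
#' @param map numeric array (NAs preserved).
#' @return Array of the same shape.
#' @export
invert_map <- function(map) {
  m <- max(map[is.finite(map)])
  out <- m - map
  out[!is.finite(map)] <- map[!is.finite(map)]
  out
}

# Threshold and plateau/background estimates for a 1D profile.
profile_levels <- function(profile) {
  fin <- profile[is.finite(profile)]
  if (!length(fin)) stop("measurement failed: empty profile", call. = FALSE)
  n <- length(profile)
  k <- max(1, round(0.1 * n))
  bg <- stats::median(c(profile[seq_len(k)], profile[n - seq_len(k) + 1]),
                      na.rm = TRUE)
  hi <- fin[fin > bg + 0.5 * (max(fin) - bg)]
  if (!length(hi)) stop("measurement failed: no plateau found", call. = FALSE)
  plateau <- stats::median(hi)
  list(background = bg, plateau = plateau,
       threshold = bg + 0.5 * (plateau - bg))
}

#' Sub-pixel edge positions on a 1D intensity profile
#'
#' Locates the two opposing edges of a bright plateau as the positions where
#' intensity crosses 50 % of the plateau-to-background contrast (plateau and
#' background estimated as medians), with linear interpolation between
#' samples. Invariant to global intensity scale and offset. With
#' `strict = TRUE` (the default) a profile with more than one plateau is an
#' error; with `strict = FALSE` the outermost crossings are returned, which
#' is what phantom-interior profiles with internal structure need.
#'
#' @param profile numeric vector, a bright plateau between dark flanks.
#' @param pixel_mm sample spacing (mm).
#' @param strict error on multiple plateaus (ambiguous profile).
#' @return List with `left`, `right` (fractional 1-based sample positions)
#'   and `length_mm = (right - left) * pixel_mm`.
#' @export
edge_positions <- function(profile, pixel_mm = 1, strict = TRUE) {
  lv <- profile_levels(profile)
  above <- profile >= lv$threshold
  above[!is.finite(profile)] <- FALSE
  r <- rle(above)
  runs <- sum(r$values & r$lengths >= 2)
  if (runs == 0) stop("measurement failed: no threshold crossing",
                      call. = FALSE)
  if (strict && runs > 1)
    stop("ambiguous profile: multiple plateaus detected", call. = FALSE)
  i_first <- which(above)[1]
  i_last <- max(which(above))
  interp <- function(i, j) {
    # crossing between samples i and j (|i-j| = 1)
    if (i < 1 || j > length(profile) || !is.finite(profile[i]))
      return(NA_real_)
    i + (lv$threshold - profile[i]) / (profile[j] - profile[i]) * (j - i)
  }
  left <- if (i_first == 1) 1 else interp(i_first - 1, i_first)
  right <- if (i_last == length(profile)) i_last
           else interp(i_last + 1, i_last)
  if (!is.finite(left) || !is.finite(right))
    stop("measurement failed: edge at profile boundary", call. = FALSE)
  list(left = left, right = right,
       length_mm = (right - left) * pixel_mm)
}

# Average a band of profile lines from a slice. axis = "col" profiles run
# along columns (one value per column); axis = "row" along rows. The band
# average is lightly Gaussian-smoothed so the partial-volume edge ramp
# (about one pixel wide) spans both samples used by the sub-pixel
# interpolation in edge_positions().
band_profile <- function(slice, axis, center, half_width, smooth_px = 1) {
  idx <- pmax(1, pmin(if (axis == "col") nrow(slice) else ncol(slice),
                      round(center) + seq(-half_width, half_width)))
  p <- if (axis == "col") colMeans(slice[idx, , drop = FALSE])
  else rowMeans(slice[, idx, drop = FALSE])
  if (smooth_px > 0) {
    r <- ceiling(4 * smooth_px)
    k <- stats::dnorm(seq(-r, r), 0, smooth_px)
    p <- as.numeric(stats::filter(c(rep(p[1], r), p, rep(p[length(p)], r)),
                                  k / sum(k), sides = 2))[r + seq_along(p)]
  }
  p
}

#' Measure internal phantom dimensions on an image stack
#'
#' Implements opposing-edge dimension measurement: selects the slice with the
#' largest in-plane phantom area, averages a small band of intensity profile
#' lines, and measures the distance between the outermost 50 %-contrast
#' edge crossings with sub-pixel interpolation. One horizontal and one
#' vertical in-plane dimension are returned per scan, tagged with their
#' phantom axis and encoding role. Vertical (y) profiles are taken in a
#' lateral band offset from the phantom centre so the tape and central
#' compartment do not confound the measurement.
#'
#' @param stack an `mri_stack`.
#' @param band_lines number of profile lines averaged (odd).
#' @param y_band_frac lateral position of the y-measurement band as a
#'   fraction of the measured horizontal interior extent, from the left
#'   interior edge.
#' @param scan_id identifier recorded with the measurements.
#' @return A data.frame of measurement records with columns `scan_id`,
#'   `kind`, `direction`, `plane`, `encoding_role`, `value` (mm).
#' @export
measure_dimensions <- function(stack, band_lines = 5, y_band_frac = 0.15,
                               scan_id = stack$preset_name) {
  stopifnot(inherits(stack, "mri_stack"))
  axes <- plane_axes(stack$plane)
  dat <- stack$data
  # middle slice: maximal in-plane area above half-max
  gl <- profile_levels(as.vector(dat))
  area <- apply(dat >= gl$threshold, 3, sum)
  if (max(area) == 0)
    stop("measurement failed: phantom not found in any slice", call. = FALSE)
  sl <- dat[, , central_max_slice(area)]
  hw <- (band_lines - 1) %/% 2

  mask <- sl >= gl$threshold
  ctr_row <- mean(which(rowSums(mask) > 0))
  ctr_col <- mean(which(colSums(mask) > 0))

  # horizontal dimension (columns axis)
  ph <- band_profile(sl, "col", ctr_row, hw)
  eh <- edge_positions(ph, stack$grid$pixel_dx, strict = FALSE)

  # vertical dimension (rows axis)
  v_axis <- axes[["row"]]
  if (v_axis == "y") {
    # lateral band offset from the left interior edge
    col_c <- eh$left + y_band_frac * (eh$right - eh$left)
  } else {
    col_c <- ctr_col
  }
  pv <- band_profile(sl, "row", col_c, hw)
  ev <- edge_positions(pv, stack$grid$pixel_dy, strict = FALSE)

  role <- function(axis)
    if (axis == stack$freq_axis) "frequency"
    else if (axis == stack$phase_axis) "phase" else "slice"
  data.frame(scan_id = scan_id, kind = "dimension",
             direction = c(axes[["col"]], axes[["row"]]),
             plane = stack$plane,
             encoding_role = c(role(axes[["col"]]), role(axes[["row"]])),
             value = c(eh$length_mm, ev$length_mm),
             stringsAsFactors = FALSE)
}
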