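#' Geometric distortion model for simulated scans
#'
#' Distortion is applied as a coordinate mapping of the phantom geometry prior
#' to rasterization (emulating gradient miscalibration), so the implanted
#' ground truth is exact: a `+2 %` scale error on x makes every measured
#' x-dimension exactly `1.02` times its true value on a noiseless scan.
#'
#' @param scale_error_pct length-3 numeric, per-phantom-axis (x, y, z) linear
#'   scaling error in percent. Positive values make the phantom appear larger.
#' @param nonlinear optional smooth displacement field, from
#'   [nonlinear_bspline()] or [nonlinear_bump()]; apparent displacement in mm
#'   added on top of the linear scaling.
#' @param encoding_shift_mm rigid shift (mm) applied along the frequency
#'   encoding axis of each scan (a positional offset, not a scaling).
#' @param max_nonlinear_mm bound on the nonlinear field magnitude; exceeding
#'   it is an error (guards against unphysical fields, default 0.3 mm).
#' @return An object of class `distortion_model`. The zero model is the
#'   identity mapping.
#' @export
distortion_model <- function(scale_error_pct = c(0, 0, 0),
                             nonlinear = NULL,
                             encoding_shift_mm = 0,
                             max_nonlinear_mm = 0.3) {
  scale_error_pct <- rep_len(as.numeric(scale_error_pct), 3)
  if (any(scale_error_pct <= -100))
    stop("scale errors must be > -100 %", call. = FALSE)
  if (!is.null(nonlinear)) {
    stopifnot(inherits(nonlinear, "nonlinear_field"))
    if (nonlinear$max_mm > max_nonlinear_mm + 1e-9)
      stop(sprintf("nonlinear field magnitude %.3f mm exceeds bound %.3f mm",
                   nonlinear$max_mm, max_nonlinear_mm), call. = FALSE)
  }
  structure(list(scale_error_pct = scale_error_pct, nonlinear = nonlinear,
                 encoding_shift_mm = encoding_shift_mm,
                 max_nonlinear_mm = max_nonlinear_mm),
            class = "distortion_model")
}

#' Smooth nonlinear displacement fields
#'
#' `nonlinear_bspline` defines a 3D displacement field on a uniform cubic
#' B-spline control lattice (`coef` has dimensions `nx x ny x nz x 3`, control
#' displacements in mm per phantom axis). `nonlinear_bump` is a convenience
#' constructor for a single smooth Gaussian bump.
#'
#' @param origin mm position (x, y, z) of the first control point.
#' @param spacing_mm control point spacing (mm).
#' @param coef numeric array `nx x ny x nz x 3` of control displacements (mm).
#' @return An object of class `nonlinear_field` with an `eval(x, y, z)`
#'   closure returning the displacement components.
#' @export
nonlinear_bspline <- function(origin, spacing_mm, coef) {
  stopifnot(length(dim(coef)) == 4, dim(coef)[4] == 3, spacing_mm > 0)
  nd <- dim(coef)[1:3]
  bs_basis <- function(t) {
    cbind((1 - t)^3 / 6,
          (3 * t^3 - 6 * t^2 + 4) / 6,
          (-3 * t^3 + 3 * t^2 + 3 * t + 1) / 6,
          t^3 / 6)
  }
  eval_field <- function(x, y, z) {
    n <- max(length(x), length(y), length(z))
    p <- list(rep_len(x, n), rep_len(y, n), rep_len(z, n))
    idx <- vector("list", 3); w <- vector("list", 3)
    for (a in 1:3) {
      s <- (p[[a]] - origin[a]) / spacing_mm
      i0 <- floor(s)
      w[[a]] <- bs_basis(s - i0)
      idx[[a]] <- i0                      # control indices i0 .. i0+3 (0-based)
    }
    ux <- numeric(n); uy <- numeric(n); uz <- numeric(n)
    for (di in 0:3) for (dj in 0:3) for (dk in 0:3) {
      ii <- pmin(pmax(idx[[1]] + di - 1, 0), nd[1] - 1) + 1
      jj <- pmin(pmax(idx[[2]] + dj - 1, 0), nd[2] - 1) + 1
      kk <- pmin(pmax(idx[[3]] + dk - 1, 0), nd[3] - 1) + 1
      wt <- w[[1]][, di + 1] * w[[2]][, dj + 1] * w[[3]][, dk + 1]
      lin <- ii + nd[1] * (jj - 1 + nd[2] * (kk - 1))
      ux <- ux + wt * coef[lin]
      uy <- uy + wt * coef[lin + prod(nd)]
      uz <- uz + wt * coef[lin + 2 * prod(nd)]
    }
    list(x = ux, y = uy, z = uz)
  }
  # bound: control-polygon magnitude bounds the spline
  mags <- sqrt(coef[, , , 1]^2 + coef[, , , 2]^2 + coef[, , , 3]^2)
  structure(list(eval = eval_field, max_mm = max(mags)),
            class = "nonlinear_field")
}

#' @rdname nonlinear_bspline
#' @param center mm position (x, y, z) of the bump centre.
#' @param sigma_mm Gaussian width of the bump (mm).
#' @param amplitude_mm length-3 displacement (mm) at the bump centre.
#' @export
nonlinear_bump <- function(center, sigma_mm, amplitude_mm) {
  amplitude_mm <- rep_len(as.numeric(amplitude_mm), 3)
  eval_field <- function(x, y, z) {
    n <- max(length(x), length(y), length(z))
    x <- rep_len(x, n); y <- rep_len(y, n); z <- rep_len(z, n)
    g <- exp(-((x - center[1])^2 + (y - center[2])^2 + (z - center[3])^2) /
               (2 * sigma_mm^2))
    list(x = amplitude_mm[1] * g, y = amplitude_mm[2] * g,
         z = amplitude_mm[3] * g)
  }
  structure(list(eval = eval_field, max_mm = sqrt(sum(amplitude_mm^2))),
            class = "nonlinear_field")
}

# Build the sampling warp: image-frame phantom-axis coordinates -> true
# phantom coordinates. shift_axis/shift_mm implement the frequency-encoding
# shift in the image frame.
make_warp <- function(distortion, shift_axis = NULL, shift_mm = 0) {
  if (is.null(distortion))
    distortion <- distortion_model()
  sc <- 1 + distortion$scale_error_pct / 100
  nl <- distortion$nonlinear
  function(x, y, z) {
    if (!is.null(shift_axis) && shift_mm != 0) {
      if (shift_axis == "x") x <- x - shift_mm
      else if (shift_axis == "y") y <- y - shift_mm
      else z <- z - shift_mm
    }
    if (!is.null(nl)) {
      u <- nl$eval(x, y, z)
      x <- x - u$x; y <- y - u$y; z <- z - u$z
    }
    list(x = x / sc[1], y = y / sc[2], z = z / sc[3])
  }
}

#' Noise and intensity-inhomogeneity model for simulated scans
#'
#' SNR is defined as the plateau (fully solution-filled voxel) signal divided
#' by the Gaussian noise sigma of the underlying complex channels; the
#' magnitude image then carries Rician noise. The bias field is a
#' multiplicative second-order 2D polynomial per slice (default off),
#' standing in for receive-coil inhomogeneity.
#'
#' @param snr plateau signal / noise sigma; `Inf` for noiseless.
#' @param bias_field optional length-5 coefficients `(cu, cv, cuu, cuv, cvv)`
#'   of `1 + cu*u + cv*v + cuu*u^2 + cuv*u*v + cvv*v^2` with `u, v` the
#'   in-plane coordinates normalized to `[-1, 1]`.
#' @param seed integer RNG seed; the same seed gives bit-identical output.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(snr = Inf, bias_field = NULL, seed = 1L) {
  if (!is.numeric(snr) || length(snr) != 1 || snr <= 0)
    stop("snr must be a single positive number (Inf for noiseless)",
         call. = FALSE)
  if (!is.null(bias_field)) bias_field <- rep_len(as.numeric(bias_field), 5)
  structure(list(snr = snr, bias_field = bias_field, seed = as.integer(seed)),
            class = "noise_model")
}
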