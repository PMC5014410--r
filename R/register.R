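# Bilinear sampling of matrix `img` at fractional (row, col) indices;
# positions outside the image return `fill`.
bilinear_sample <- function(img, ri, ci, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- floor(ri); c0 <- floor(ci)
  fr <- ri - r0; fc <- ci - c0
  ok <- r0 >= 1 & r0 <= nr - 1 & c0 >= 1 & c0 <= nc - 1
  out <- rep(fill, length(ri))
  if (any(ok)) {
    r0 <- r0[ok]; c0 <- c0[ok]; frk <- fr[ok]; fck <- fc[ok]
    i00 <- r0 + (c0 - 1) * nr
    v <- img[i00] * (1 - frk) * (1 - fck) +
      img[i00 + 1] * frk * (1 - fck) +
      img[i00 + nr] * (1 - frk) * fck +
      img[i00 + nr + 1] * frk * fck
    out[ok] <- v
  }
  out
}

# Keys cubic-convolution kernel (a = -0.5), the conventional bicubic filter.
cubic_kernel <- function(t) {
  t <- abs(t); a <- -0.5
  ifelse(t <= 1, (a + 2) * t^3 - (a + 3) * t^2 + 1,
         ifelse(t < 2, a * t^3 - 5 * a * t^2 + 8 * a * t - 4 * a, 0))
}

#' Bicubic image resampling
#'
#' Separable cubic-convolution interpolation onto a new grid size, used to
#' match in-plane resolutions before registration.
#'
#' @param img numeric matrix.
#' @param out_rows,out_cols output size.
#' @return Matrix `out_rows x out_cols`.
#' @export
resample_bicubic <- function(img, out_rows, out_cols) {
  map1 <- function(n_in, n_out) (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
  wmat <- function(pos, n_in) {
    W <- matrix(0, length(pos), n_in)
    for (k in -1:2) {
      idx <- pmin(pmax(floor(pos) + k, 1), n_in)
      w <- cubic_kernel(pos - (floor(pos) + k))
      W[cbind(seq_along(pos), idx)] <- W[cbind(seq_along(pos), idx)] + w
    }
    W / rowSums(W)
  }
  Wr <- wmat(map1(nrow(img), out_rows), nrow(img))
  Wc <- wmat(map1(ncol(img), out_cols), ncol(img))
  Wr %*% img %*% t(Wc)
}

# Normalize intensities so background ~ 0 and plateau ~ 1.
normalize_intensity <- function(img) {
  lv <- profile_levels(as.vector(img))
  (img - lv$background) / (lv$plateau - lv$background)
}

# Pixel-centre coordinates (mm, image-centred) of a matrix.
image_coords_mm <- function(img, pixel_mm) {
  list(x = (seq_len(ncol(img)) - (ncol(img) + 1) / 2) * pixel_mm,
       y = (seq_len(nrow(img)) - (nrow(img) + 1) / 2) * pixel_mm)
}

#' Rigid 2D registration by intensity
#'
#' Estimates the rotation and translation aligning `moving` to `fixed` by
#' minimizing the mean squared intensity difference, with multi-start
#' Nelder-Mead local optimization (rotation starts at -10, 0, +10 degrees;
#' translation initialized from the bright-region centroid shift). Both
#' images are intensity-normalized (background 0, plateau 1) and lightly
#' blurred to widen the capture range before matching.
#'
#' @param moving,fixed numeric matrices of equal size.
#' @param pixel_mm in-plane pixel size (mm), shared by both images.
#' @param blur_px Gaussian pre-blur sigma in pixels.
#' @return List with `theta_deg`, `tx_mm`, `ty_mm` (pull-back transform:
#'   `moving` sampled at `R(theta) x + t`), the attained `residual` (RMS
#'   intensity difference) and the optimizer diagnostics.
#' @export
register_rigid <- function(moving, fixed, pixel_mm, blur_px = 1) {
  stopifnot(identical(dim(moving), dim(fixed)))
  mv <- normalize_intensity(moving); fx <- normalize_intensity(fixed)
  if (blur_px > 0) {
    mv <- EBImage::gblur(mv, sigma = blur_px)
    fx <- EBImage::gblur(fx, sigma = blur_px)
  }
  co <- image_coords_mm(fx, pixel_mm)
  X <- matrix(co$x, nrow(fx), ncol(fx), byrow = TRUE)
  Y <- matrix(co$y, nrow(fx), ncol(fx))
  centroid <- function(img) {
    w <- pmax(img, 0); s <- sum(w)
    c(sum(w * X) / s, sum(w * Y) / s)
  }
  t0 <- centroid(mv) - centroid(fx)
  cost <- function(p) {
    th <- p[1] * pi / 180
    xr <- cos(th) * X - sin(th) * Y + p[2]
    yr <- sin(th) * X + cos(th) * Y + p[3]
    w <- bilinear_sample(mv, yr / pixel_mm + (nrow(mv) + 1) / 2,
                         xr / pixel_mm + (ncol(mv) + 1) / 2)
    mean((w - as.vector(fx))^2)
  }
  best <- NULL
  for (th0 in c(-10, 0, 10)) {
    fit <- stats::optim(c(th0, t0[1], t0[2]), cost, method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-10))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (!is.finite(best$value))
    stop("rigid registration diverged; check image contents", call. = FALSE)
  list(theta_deg = best$par[1], tx_mm = best$par[2], ty_mm = best$par[3],
       residual = sqrt(best$value), value = best$value,
       convergence = best$convergence)
}

#' Resample an image through a rigid transform
#'
#' @param moving numeric matrix.
#' @param params result of [register_rigid()] (or a list with `theta_deg`,
#'   `tx_mm`, `ty_mm`).
#' @param pixel_mm pixel size (mm).
#' @return The transformed image on the same grid.
#' @export
apply_rigid <- function(moving, params, pixel_mm) {
  co <- image_coords_mm(moving, pixel_mm)
  X <- matrix(co$x, nrow(moving), ncol(moving), byrow = TRUE)
  Y <- matrix(co$y, nrow(moving), ncol(moving))
  th <- params$theta_deg * pi / 180
  xr <- cos(th) * X - sin(th) * Y + params$tx_mm
  yr <- sin(th) * X + cos(th) * Y + params$ty_mm
  matrix(bilinear_sample(moving, yr / pixel_mm + (nrow(moving) + 1) / 2,
                         xr / pixel_mm + (ncol(moving) + 1) / 2),
         nrow(moving), ncol(moving))
}

#' Free-form (B-spline) 2D registration
#'
#' Nonrigid alignment of a (rigidly pre-aligned) image to a reference by a
#' tensor-product cubic B-spline free-form deformation, minimizing the mean
#' squared intensity difference plus a bending (second-difference) penalty
#' on the control lattice, with analytic gradients and L-BFGS-B. The
#' optimization starts from the zero field, so the attained residual never
#' exceeds the rigid-stage residual; non-convergence within the iteration
#' cap returns the best field found, with a warning.
#'
#' @param moving,fixed numeric matrices of equal size (pre-aligned).
#' @param pixel_mm pixel size (mm).
#' @param control_spacing_mm control point spacing (mm).
#' @param lambda bending penalty weight.
#' @param max_iter L-BFGS-B iteration cap.
#' @param normalize intensity-normalize the inputs first.
#' @return A `displacement_field`: `dx`, `dy` (mm, per fixed pixel, pointing
#'   from the fixed grid to the matching moving-image location), `pixel_mm`,
#'   attained `residual`, initial `residual0` and provenance.
#' @export
register_bspline <- function(moving, fixed, pixel_mm,
                             control_spacing_mm = 8 * pixel_mm,
                             lambda = 0.01, max_iter = 200,
                             normalize = TRUE) {
  stopifnot(identical(dim(moving), dim(fixed)))
  mv <- if (normalize) normalize_intensity(moving) else moving
  fx <- if (normalize) normalize_intensity(fixed) else fixed
  nr <- nrow(fx); nc <- ncol(fx)
  co <- image_coords_mm(fx, pixel_mm)

  # cubic B-spline basis matrix: positions (mm) x control points
  basis_matrix <- function(pos, spacing) {
    i0 <- floor(min(pos) / spacing) - 2
    i1 <- ceiling(max(pos) / spacing) + 2
    centers <- (i0:i1) * spacing
    t <- outer(pos, centers, function(p, c) abs(p - c) / spacing)
    B <- ifelse(t < 1, (4 - 6 * t^2 + 3 * t^3) / 6,
                ifelse(t < 2, (2 - t)^3 / 6, 0))
    B
  }
  Br <- basis_matrix(co$y, control_spacing_mm)   # nr x kr
  Bc <- basis_matrix(co$x, control_spacing_mm)   # nc x kc
  kr <- ncol(Br); kc <- ncol(Bc)

  # second-difference (bending) operators on the lattice
  d2 <- function(k) {
    if (k < 3) return(matrix(0, 0, k))
    D <- matrix(0, k - 2, k)
    for (i in seq_len(k - 2)) D[i, i:(i + 2)] <- c(1, -2, 1)
    D
  }
  Dr <- d2(kr); Dc <- d2(kc)

  # moving-image intensity gradients (per mm), sampled where we warp
  grad_img <- function(img) {
    gx <- img; gy <- img
    gx[, 2:(nc - 1)] <- (img[, 3:nc] - img[, 1:(nc - 2)]) / (2 * pixel_mm)
    gx[, c(1, nc)] <- 0
    gy[2:(nr - 1), ] <- (img[3:nr, ] - img[1:(nr - 2), ]) / (2 * pixel_mm)
    gy[c(1, nr), ] <- 0
    list(gx = gx, gy = gy)
  }
  G <- grad_img(mv)
  X <- matrix(co$x, nr, nc, byrow = TRUE)
  Y <- matrix(co$y, nr, nc)
  Npx <- nr * nc

  unpack <- function(p) list(Cx = matrix(p[seq_len(kr * kc)], kr, kc),
                             Cy = matrix(p[-seq_len(kr * kc)], kr, kc))
  warp_eval <- function(C) Br %*% C %*% t(Bc)
  sample_at <- function(img, Ux, Uy)
    matrix(bilinear_sample(img, (Y + Uy) / pixel_mm + (nr + 1) / 2,
                           (X + Ux) / pixel_mm + (nc + 1) / 2), nr, nc)

  fn <- function(p) {
    C <- unpack(p)
    Ux <- warp_eval(C$Cx); Uy <- warp_eval(C$Cy)
    W <- sample_at(mv, Ux, Uy)
    pen <- sum((Dr %*% C$Cx)^2) + sum((C$Cx %*% t(Dc))^2) +
      sum((Dr %*% C$Cy)^2) + sum((C$Cy %*% t(Dc))^2)
    mean((W - fx)^2) + lambda * pen
  }
  gr <- function(p) {
    C <- unpack(p)
    Ux <- warp_eval(C$Cx); Uy <- warp_eval(C$Cy)
    W <- sample_at(mv, Ux, Uy)
    D <- W - fx
    Gxw <- sample_at(G$gx, Ux, Uy); Gyw <- sample_at(G$gy, Ux, Uy)
    gCx <- 2 / Npx * t(Br) %*% (D * Gxw) %*% Bc +
      2 * lambda * (t(Dr) %*% (Dr %*% C$Cx) + C$Cx %*% t(Dc) %*% Dc)
    gCy <- 2 / Npx * t(Br) %*% (D * Gyw) %*% Bc +
      2 * lambda * (t(Dr) %*% (Dr %*% C$Cy) + C$Cy %*% t(Dc) %*% Dc)
    c(as.vector(gCx), as.vector(gCy))
  }

  p0 <- numeric(2 * kr * kc)
  res0 <- sqrt(fn(p0))
  fit <- stats::optim(p0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = max_iter))
  if (fit$convergence != 0)
    warning("B-spline registration did not fully converge; returning the ",
            "best field found", call. = FALSE)
  C <- unpack(fit$par)
  structure(list(dx = warp_eval(C$Cx), dy = warp_eval(C$Cy),
                 pixel_mm = pixel_mm,
                 residual = sqrt(fit$value), residual0 = res0,
                 control_spacing_mm = control_spacing_mm, lambda = lambda,
                 convergence = fit$convergence),
            class = "displacement_field")
}

#' Per-pixel Euclidean displacement magnitude
#'
#' @param field a `displacement_field` (or a list with `dx`, `dy` in mm).
#' @return Matrix of `sqrt(dx^2 + dy^2)` (mm); non-negative, invariant to
#'   axis sign conventions.
#' @export
displacement_magnitude <- function(field) {
  if (!all(is.finite(field$dx)) || !all(is.finite(field$dy)))
    stop("displacement field contains non-finite values", call. = FALSE)
  sqrt(field$dx^2 + field$dy^2)
}

#' @export
print.displacement_field <- function(x, ...) {
  m <- displacement_magnitude(x)
  cat(sprintf("displacement_field %d x %d: |u| median %.3g mm, max %.3g mm (residual %.3g, rigid-stage %.3g)\n",
              nrow(x$dx), ncol(x$dx), stats::median(m), max(m),
              x$residual, x$residual0))
  invisible(x)
}

#' End-to-end distortion map for one slice
#'
#' Mirrors the deformation-mapping workflow: intensity normalization, rigid
#' alignment of the MRI slice to the reference, bicubic resolution matching
#' (if needed), free-form B-spline refinement, and the per-pixel Euclidean
#' displacement-magnitude map.
#'
#' @param mri_slice numeric matrix (one MRI slice).
#' @param reference numeric matrix (CT-derived or rasterized ground truth).
#' @param pixel_mm pixel size of the reference grid (mm).
#' @param mri_pixel_mm pixel size of the MRI slice; resampled to
#'   `pixel_mm` when different.
#' @param ... passed to [register_bspline()].
#' @return List with the rigid `params`, the `field` and the `magnitude`
#'   map (mm).
#' @export
deformation_map <- function(mri_slice, reference, pixel_mm,
                            mri_pixel_mm = pixel_mm, ...) {
  if (abs(mri_pixel_mm - pixel_mm) > 1e-9) {
    sc <- mri_pixel_mm / pixel_mm
    mri_slice <- resample_bicubic(mri_slice,
                                  round(nrow(mri_slice) * sc),
                                  round(ncol(mri_slice) * sc))
  }
  # pad/crop to the reference grid
  mri_slice <- fit_to_dims(mri_slice, dim(reference))
  rig <- register_rigid(mri_slice, reference, pixel_mm)
  aligned <- apply_rigid(normalize_intensity(mri_slice), rig, pixel_mm)
  fld <- register_bspline(aligned, normalize_intensity(reference), pixel_mm,
                          normalize = FALSE, ...)
  list(params = rig, field = fld, magnitude = displacement_magnitude(fld))
}

# centre-crop or zero-pad a matrix to target dims
fit_to_dims <- function(img, d) {
  out <- matrix(0, d[1], d[2])
  r <- min(nrow(img), d[1]); c <- min(ncol(img), d[2])
  sr_in <- floor((nrow(img) - r) / 2); sc_in <- floor((ncol(img) - c) / 2)
  sr_out <- floor((d[1] - r) / 2); sc_out <- floor((d[2] - c) / 2)
  out[sr_out + seq_len(r), sc_out + seq_len(c)] <-
    img[sr_in + seq_len(r), sc_in + seq_len(c)]
  out
}
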