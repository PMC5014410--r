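# Material classes used by the rasterizer and simulator.
PHANTOM_CLASSES <- c(exterior = 0L, plastic = 1L, shell_solution = 2L,
                     compartment_solution = 3L, tape = 4L)

#' Classify points in phantom coordinates
#'
#' Vectorized material lookup at arbitrary (x, y, z) positions (mm, phantom
#' centred). Used by the rasterizer and the scan simulator; distortion models
#' warp coordinates before calling this, so simulated geometric errors are
#' exact by construction.
#'
#' @param spec a [phantom_spec()].
#' @param x,y,z numeric vectors (recycled to a common length), mm.
#' @return Integer class codes: 0 exterior, 1 plastic, 2 shell solution,
#'   3 compartment solution, 4 tape.
#' @keywords internal
classify_points <- function(spec, x, y, z) {
  n <- max(length(x), length(y), length(z))
  x <- rep_len(x, n); y <- rep_len(y, n); z <- rep_len(z, n)
  hx <- spec$interior_x / 2; hy <- spec$interior_y / 2
  hz <- spec$interior_z / 2
  w <- spec$wall_thickness
  out <- integer(n)                               # exterior

  ax <- abs(x); ay <- abs(y); az <- abs(z)
  in_outer <- ax <= hx + w & ay <= hy + w & az <= hz + w
  in_int   <- ax <= hx & ay <= hy & az <= hz
  out[in_outer] <- PHANTOM_CLASSES[["plastic"]]
  out[in_int]   <- PHANTOM_CLASSES[["shell_solution"]]

  # tape slab on the interior base, centred, square extent
  te <- spec$tape_extent / 2
  tape <- in_int & y <= -hy + spec$tape_thickness & ax <= te & az <= te
  out[tape] <- PHANTOM_CLASSES[["tape"]]

  # frustum cavity: axis along y, wide end (r_bottom) at the bottom,
  # sitting on the tape
  y0 <- -hy + spec$tape_thickness
  h  <- spec$frustum_height
  cw <- spec$compartment_wall
  in_span <- in_int & y >= y0 & y <= y0 + h
  t_frac <- pmin(pmax((y - y0) / h, 0), 1)
  r <- spec$frustum_r_bottom + (spec$frustum_r_top - spec$frustum_r_bottom) * t_frac
  rho2 <- x^2 + z^2
  out[in_span & rho2 <= (r + cw)^2] <- PHANTOM_CLASSES[["plastic"]]
  out[in_span & rho2 <= r^2] <- PHANTOM_CLASSES[["compartment_solution"]]

  # plastic cap above the cavity when the frustum stops short of the ceiling
  if (y0 + h < hy - 1e-9) {
    cap <- in_int & y > y0 + h & y <= y0 + h + cw &
      rho2 <= (spec$frustum_r_top + cw)^2
    out[cap] <- PHANTOM_CLASSES[["plastic"]]
  }

  # orientation mark: small slot carved out of the base plastic near +x
  if (isTRUE(spec$orientation_mark)) {
    notch <- in_outer & !in_int & y < -hy - w + 0.4 &
      x >= hx - 1.5 & x <= hx - 0.5 & az <= 0.5
    out[notch] <- PHANTOM_CLASSES[["exterior"]]
  }
  out
}

# Fraction of the interval [c - w/2, c + w/2] lying inside [a, b]:
# the exact box-filter response of a slab, valid for any slab thickness.
slab_occ <- function(c, a, b, w) {
  pmax(0, pmin(b, c + w / 2) - pmax(a, c - w / 2)) / w
}

# Linear-ramp soft indicator of `d >= 0` for a surface whose box-filter
# support along the normal is `l`.
ramp_occ <- function(d, l) pmin(pmax(d / l + 0.5, 0), 1)

#' Analytic partial-volume occupancy of the solution compartments
#'
#' Per-voxel fractional occupancy of solution (shell + compartment) and of
#' the compartment alone, for voxels of size `(wx, wy, wz)` (mm, phantom
#' axes) centred at the given points. Axis-aligned faces (interior box, tape
#' slab) use exact box-filter interval overlaps; the curved frustum surface
#' uses a linear ramp over its normal-projected box-filter support. This is
#' the simulator's signal model: it is free of the sampling quantization a
#' finite supersampling lattice would impose on sub-pixel edge positions.
#'
#' @param spec a [phantom_spec()].
#' @param x,y,z voxel-centre coordinates (mm), recycled to common length.
#' @param wx,wy,wz voxel extents (mm) along the phantom axes.
#' @return List with numeric vectors `solution` and `compartment` in [0, 1].
#' @keywords internal
solution_occupancy <- function(spec, x, y, z, wx, wy, wz) {
  n <- max(length(x), length(y), length(z))
  x <- rep_len(x, n); y <- rep_len(y, n); z <- rep_len(z, n)
  hx <- spec$interior_x / 2; hy <- spec$interior_y / 2
  hz <- spec$interior_z / 2
  inside <- slab_occ(x, -hx, hx, wx) * slab_occ(y, -hy, hy, wy) *
    slab_occ(z, -hz, hz, wz)

  te <- spec$tape_extent / 2
  tape <- slab_occ(y, -hy, -hy + spec$tape_thickness, wy) *
    slab_occ(x, -te, te, wx) * slab_occ(z, -te, te, wz)

  y0 <- -hy + spec$tape_thickness
  h <- spec$frustum_height; cw <- spec$compartment_wall
  yspan <- slab_occ(y, y0, y0 + h, wy)
  t_frac <- pmin(pmax((y - y0) / h, 0), 1)
  r <- spec$frustum_r_bottom +
    (spec$frustum_r_top - spec$frustum_r_bottom) * t_frac
  rho <- sqrt(x^2 + z^2)
  # box-filter support of the lateral surface along its (in-plane) normal
  l_r <- pmax((abs(x) * wx + abs(z) * wz) / pmax(rho, 1e-9), 1e-9)
  cavity <- ramp_occ(r - rho, l_r) * yspan
  # the exclusion wall extends down through the tape to the base, so the
  # wall/tape/cavity decomposition stays consistent at the compartment floor
  wall_out <- ramp_occ(r + cw - rho, l_r) * slab_occ(y, -hy, y0 + h, wy)

  solution <- inside * (1 - tape) * (1 - wall_out) + cavity
  list(solution = pmin(pmax(solution, 0), 1),
       compartment = pmin(pmax(cavity, 0), 1))
}

# Analytic solid (plastic + tape) occupancy for CT-like simulation: exact
# box-filter overlaps for the outer shell, interior box, tape and notch;
# normal-projected ramps for the frustum wall ring.
solid_occupancy <- function(spec, x, y, z, wx, wy, wz) {
  n <- max(length(x), length(y), length(z))
  x <- rep_len(x, n); y <- rep_len(y, n); z <- rep_len(z, n)
  hx <- spec$interior_x / 2; hy <- spec$interior_y / 2
  hz <- spec$interior_z / 2; w <- spec$wall_thickness
  box <- function(ax, ay, az)
    slab_occ(x, -ax, ax, wx) * slab_occ(y, -ay, ay, wy) *
    slab_occ(z, -az, az, wz)
  solid <- box(hx + w, hy + w, hz + w) - box(hx, hy, hz)

  te <- spec$tape_extent / 2
  solid <- solid + slab_occ(y, -hy, -hy + spec$tape_thickness, wy) *
    slab_occ(x, -te, te, wx) * slab_occ(z, -te, te, wz)

  y0 <- -hy + spec$tape_thickness
  h <- spec$frustum_height; cw <- spec$compartment_wall
  t_frac <- pmin(pmax((y - y0) / h, 0), 1)
  r <- spec$frustum_r_bottom +
    (spec$frustum_r_top - spec$frustum_r_bottom) * t_frac
  rho <- sqrt(x^2 + z^2)
  l_r <- pmax((abs(x) * wx + abs(z) * wz) / pmax(rho, 1e-9), 1e-9)
  ring <- (ramp_occ(r + cw - rho, l_r) - ramp_occ(r - rho, l_r)) *
    slab_occ(y, y0, y0 + h, wy)
  solid <- solid + pmax(ring, 0)
  if (y0 + h < hy - 1e-9)
    solid <- solid + ramp_occ(spec$frustum_r_top + cw - rho, l_r) *
      slab_occ(y, y0 + h, y0 + h + cw, wy)

  if (isTRUE(spec$orientation_mark))
    solid <- solid - slab_occ(y, -hy - w, -hy - w + 0.4, wy) *
      slab_occ(x, hx - 1.5, hx - 0.5, wx) * slab_occ(z, -0.5, 0.5, wz)
  pmin(pmax(solid, 0), 1)
}

#' Rasterize the phantom onto an imaging grid
#'
#' Samples the phantom on a supersampled lattice (`supersampling` sub-samples
#' per voxel edge, voxel-centre convention) and reduces each voxel to (a) the
#' majority material class and (b) fractional occupancies of solution and of
#' the compartment, retained for the simulator's partial-volume signal model.
#'
#' @param spec a [phantom_spec()].
#' @param grid a [grid_spec()].
#' @param supersampling sub-samples per voxel edge (>= 1).
#' @param warp optional function `f(x, y, z) -> list(x, y, z)` applied to
#'   phantom-frame coordinates before classification (used to implant
#'   geometric distortion).
#' @return A `label_volume`: list with `labels` (rows x cols x slices integer
#'   array), `occ_solution` and `occ_compartment` (same shape, in `[0, 1]`),
#'   the `grid`, the class code table, and a `clipped` flag set (with a
#'   warning) when the grid does not cover the phantom.
#' @export
rasterize_phantom <- function(spec, grid, supersampling = 4, warp = NULL) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(grid, "grid_spec"))
  s <- as.integer(supersampling)
  if (s < 1) stop("supersampling must be >= 1", call. = FALSE)

  axes <- plane_axes(grid$plane)
  co <- grid_coords(grid)
  ext <- phantom_outer_extent(spec)
  cover <- c(col   = diff(range(co$col))   + grid$pixel_dx,
             row   = diff(range(co$row))   + grid$pixel_dy,
             slice = diff(range(co$slice)) + grid$slice_thickness)
  clipped <- any(cover < ext[axes] - 1e-9)
  if (clipped)
    warning("grid does not cover the phantom: geometry clipped", call. = FALSE)

  nr <- grid$matrix_rows; nc <- grid$matrix_cols; ns <- grid$n_slices
  off <- function(pitch) ((seq_len(s) - (s + 1) / 2) / s) * pitch
  col_ss <- rep(co$col, each = s) + rep(off(grid$pixel_dx), nc)
  row_ss <- rep(co$row, each = s) + rep(off(grid$pixel_dy), nr)
  # supersample point -> voxel id (row-major within a slice, as R matrices)
  vox_row <- rep(rep(seq_len(nr), each = s), times = nc * s)
  vox_col <- rep(seq_len(nc), each = s * nr * s)
  voxid <- vox_row + (vox_col - 1L) * nr
  ncl <- length(PHANTOM_CLASSES)

  labels <- array(0L, dim = c(nr, nc, ns))
  occ_sol <- array(0, dim = c(nr, nc, ns))
  occ_cmp <- array(0, dim = c(nr, nc, ns))
  rowv <- rep(row_ss, times = nc * s)
  colv <- rep(col_ss, each = nr * s)

  for (k in seq_len(ns)) {
    counts <- matrix(0, nrow = nr * nc, ncol = ncl)
    for (zo in off(grid$slice_thickness)) {
      sl <- co$slice[k] + zo
      p <- list(col = colv, row = rowv, slice = rep_len(sl, length(colv)))
      ph <- list(x = p[[which(axes == "x")]],
                 y = p[[which(axes == "y")]],
                 z = p[[which(axes == "z")]])
      if (!is.null(warp)) ph <- warp(ph$x, ph$y, ph$z)
      cls <- classify_points(spec, ph$x, ph$y, ph$z)
      tab <- tabulate(cls + 1L + ncl * (voxid - 1L), nbins = ncl * nr * nc)
      counts <- counts + matrix(tab, nrow = nr * nc, ncol = ncl, byrow = TRUE)
    }
    tot <- s^3
    lab <- max.col(counts, ties.method = "first") - 1L
    labels[, , k] <- lab
    occ_sol[, , k] <- (counts[, PHANTOM_CLASSES[["shell_solution"]] + 1L] +
                       counts[, PHANTOM_CLASSES[["compartment_solution"]] + 1L]) / tot
    occ_cmp[, , k] <- counts[, PHANTOM_CLASSES[["compartment_solution"]] + 1L] / tot
  }

  structure(list(labels = labels, occ_solution = occ_sol,
                 occ_compartment = occ_cmp, grid = grid,
                 classes = PHANTOM_CLASSES, clipped = clipped),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("label_volume: %d x %d x %d (%s plane)%s\n", d[1], d[2], d[3],
              x$grid$plane, if (x$clipped) " [clipped]" else ""))
  print(table(factor(x$labels, levels = x$classes,
                     labels = names(x$classes))))
  invisible(x)
}

#' Write a label volume or image stack as NIfTI-1
#'
#' Voxel sizes (mm) are recorded in the NIfTI header.
#'
#' @param x a `label_volume` or `mri_stack`.
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(x, path) {
  if (inherits(x, "label_volume")) {
    dat <- x$labels; g <- x$grid
  } else if (inherits(x, "mri_stack")) {
    dat <- x$data; g <- x$grid
  } else stop("unsupported object", call. = FALSE)
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- c(g$pixel_dy, g$pixel_dx, g$slice_thickness)
  RNifti::writeNifti(img, path)
  invisible(path)
}
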