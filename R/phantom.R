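#' Parametric model of the structural QA phantom
#'
#' The phantom is a small fluid-filled cuboid with a central compartment shaped
#' as a cylindrical frustum (a truncated cone), used to assess geometric
#' accuracy of small-bore MRI scanners: its internal dimensions give per-axis
#' linear scaling errors and the compartment volume gives the volumetric error.
#' All lengths are millimetres, in a phantom-centred right-handed coordinate
#' system: x and z span the square footprint, y is vertical (the frustum axis).
#' The frustum hangs from the interior ceiling, wide end down, its open base
#' sealed by a thin tape slab; a plastic wall of thickness `compartment_wall`
#' separates the compartment solution from the surrounding shell solution.
#'
#' Default interior dimensions are 12.80 x 8.45 x 12.80 mm (x, y, z). The
#' default frustum (height `interior_y - tape_thickness` = 8.25 mm, radius
#' ratio r_top/r_bottom = 0.8, r_bottom = 2.695306 mm) has the analytic volume
#' 153.14 mm^3 used as ground truth throughout the package.
#'
#' @param interior_x,interior_y,interior_z internal dimensions (mm).
#' @param frustum_r_top,frustum_r_bottom frustum radii (mm); the wide end is
#'   at the bottom by default.
#' @param frustum_height frustum height along y (mm).
#' @param wall_thickness outer plastic wall thickness (mm).
#' @param compartment_wall plastic wall around the frustum cavity (mm).
#' @param tape_thickness thickness of the signal-void tape slab sealing the
#'   compartment base (mm).
#' @param tape_extent lateral extent (square side, mm) of the tape slab.
#' @param orientation_mark logical; carve a small notch in the base plastic.
#' @return An object of class `phantom_spec`.
#' @examples
#' spec <- phantom_spec()
#' frustum_volume(spec$frustum_r_top, spec$frustum_r_bottom, spec$frustum_height)
#' true_dimension(spec, "y")
#' @export
phantom_spec <- function(interior_x = 12.80,
                         interior_y = 8.45,
                         interior_z = 12.80,
                         frustum_r_top = 2.156245,
                         frustum_r_bottom = 2.695306,
                         frustum_height = 8.25,
                         wall_thickness = 1.0,
                         compartment_wall = 1.2,
                         tape_thickness = 0.2,
                         tape_extent = 6.0,
                         orientation_mark = TRUE) {
  lens <- c(interior_x = interior_x, interior_y = interior_y,
            interior_z = interior_z, frustum_r_top = frustum_r_top,
            frustum_r_bottom = frustum_r_bottom, frustum_height = frustum_height,
            wall_thickness = wall_thickness, compartment_wall = compartment_wall,
            tape_thickness = tape_thickness, tape_extent = tape_extent)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("invalid geometry: all phantom lengths must be strictly positive",
         call. = FALSE)
  if (2 * (max(frustum_r_top, frustum_r_bottom) + compartment_wall) >
        min(interior_x, interior_z))
    stop("invalid geometry: frustum (incl. compartment wall) does not fit ",
         "laterally inside the interior", call. = FALSE)
  if (frustum_height + tape_thickness > interior_y + 1e-9)
    stop("invalid geometry: frustum_height + tape_thickness exceeds interior_y",
         call. = FALSE)
  structure(list(
    interior_x = interior_x, interior_y = interior_y, interior_z = interior_z,
    frustum_r_top = frustum_r_top, frustum_r_bottom = frustum_r_bottom,
    frustum_height = frustum_height, wall_thickness = wall_thickness,
    compartment_wall = compartment_wall, tape_thickness = tape_thickness,
    tape_extent = tape_extent, orientation_mark = isTRUE(orientation_mark)),
    class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("Structural QA phantom\n")
  cat(sprintf("  interior (x, y, z): %.2f x %.2f x %.2f mm\n",
              x$interior_x, x$interior_y, x$interior_z))
  cat(sprintf("  frustum compartment: r_bottom %.4f, r_top %.4f, height %.3f mm\n",
              x$frustum_r_bottom, x$frustum_r_top, x$frustum_height))
  cat(sprintf("  analytic compartment volume: %.2f mm^3\n",
              frustum_volume(x$frustum_r_top, x$frustum_r_bottom,
                             x$frustum_height)))
  cat(sprintf("  walls: outer %.2f mm, compartment %.2f mm; tape %.2f mm (%.1f mm extent)\n",
              x$wall_thickness, x$compartment_wall, x$tape_thickness,
              x$tape_extent))
  invisible(x)
}

#' Analytic volume of a cylindrical frustum
#'
#' V = pi * h / 3 * (r1^2 + r1 r2 + r2^2). Symmetric in the two radii;
#' reduces to a cylinder when they are equal and to a cone when one is zero.
#'
#' @param r_top,r_bottom the two radii (mm), both >= 0.
#' @param height frustum height (mm), >= 0.
#' @return Volume in mm^3.
#' @export
frustum_volume <- function(r_top, r_bottom, height) {
  if (any(!is.finite(c(r_top, r_bottom, height))) ||
      any(c(r_top, r_bottom, height) < 0))
    stop("invalid geometry: frustum radii and height must be non-negative",
         call. = FALSE)
  pi * height / 3 * (r_top^2 + r_top * r_bottom + r_bottom^2)
}

#' Ground-truth internal dimension along a phantom axis
#'
#' @param spec a [phantom_spec()].
#' @param direction one of `"x"`, `"y"`, `"z"`.
#' @return Length in mm (the caliper ground truth).
#' @export
true_dimension <- function(spec, direction = c("x", "y", "z")) {
  stopifnot(inherits(spec, "phantom_spec"))
  direction <- match.arg(direction)
  switch(direction, x = spec$interior_x, y = spec$interior_y,
         z = spec$interior_z)
}

#' Serialize / deserialize a phantom specification as YAML
#'
#' @param spec a [phantom_spec()].
#' @param path file path; for `read_phantom_spec`, a YAML file written by
#'   `write_phantom_spec`.
#' @return `write_phantom_spec` returns `path` invisibly; `read_phantom_spec`
#'   returns a `phantom_spec`.
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  do.call(phantom_spec, yaml::read_yaml(path))
}

# ---- sampling grids ---------------------------------------------------------

#' Imaging grid specification
#'
#' Describes a multi-slice 2D acquisition grid in phantom coordinates. The
#' plane fixes which phantom axes map to image columns, rows and slices:
#' axial = x (cols) x y (rows), slices along z; coronal = x x z, slices along
#' y; sagittal = z x y, slices along x. Voxel centres are used throughout and
#' by default the grid is centred on the phantom.
#'
#' @param matrix_rows,matrix_cols in-plane matrix size (pixels).
#' @param n_slices number of slices.
#' @param pixel_dx,pixel_dy in-plane pixel pitch (mm) along columns and rows.
#' @param slice_thickness slice thickness (mm); slices are contiguous.
#' @param plane `"axial"`, `"coronal"` or `"sagittal"`.
#' @param origin mm offset (col, row, slice) of the first voxel centre from
#'   the phantom centre; `NULL` centres the grid.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(matrix_rows, matrix_cols, n_slices,
                      pixel_dx, pixel_dy, slice_thickness,
                      plane = c("axial", "coronal", "sagittal"),
                      origin = NULL) {
  plane <- match.arg(plane)
  if (any(c(pixel_dx, pixel_dy, slice_thickness) <= 0))
    stop("voxel dimensions must be strictly positive", call. = FALSE)
  if (any(c(matrix_rows, matrix_cols, n_slices) < 1))
    stop("grid counts must be >= 1", call. = FALSE)
  if (is.null(origin))
    origin <- c(-(matrix_cols - 1) / 2 * pixel_dx,
                -(matrix_rows - 1) / 2 * pixel_dy,
                -(n_slices - 1) / 2 * slice_thickness)
  structure(list(matrix_rows = as.integer(matrix_rows),
                 matrix_cols = as.integer(matrix_cols),
                 n_slices = as.integer(n_slices),
                 pixel_dx = pixel_dx, pixel_dy = pixel_dy,
                 slice_thickness = slice_thickness,
                 plane = plane, origin = origin),
            class = "grid_spec")
}

# Phantom-axis names mapped to image (col, row, slice) axes for each plane.
plane_axes <- function(plane) {
  switch(plane,
         axial    = c(col = "x", row = "y", slice = "z"),
         coronal  = c(col = "x", row = "z", slice = "y"),
         sagittal = c(col = "z", row = "y", slice = "x"),
         stop("unsupported plane: ", plane, call. = FALSE))
}

# Voxel-centre coordinates (mm, image axes) of a grid.
grid_coords <- function(grid) {
  list(col   = grid$origin[1] + (seq_len(grid$matrix_cols) - 1) * grid$pixel_dx,
       row   = grid$origin[2] + (seq_len(grid$matrix_rows) - 1) * grid$pixel_dy,
       slice = grid$origin[3] + (seq_len(grid$n_slices) - 1) * grid$slice_thickness)
}

# Outer physical extent of the phantom along each axis (mm).
phantom_outer_extent <- function(spec) {
  c(x = spec$interior_x, y = spec$interior_y, z = spec$interior_z) +
    2 * spec$wall_thickness
}
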