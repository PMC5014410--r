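#' Segment the central compartment in an axial stack
#'
#' Per-slice thresholding at 50 % between background and plateau intensity,
#' keeping the connected component that contains the stack's central region.
#' Segmentation starts from the slice with the largest phantom area, where
#' the component containing the image centre is taken, and is propagated
#' slice-by-slice outwards by maximal overlap with the previous slice's mask.
#' The plateau is re-estimated per slice from the pixels under the
#' propagated footprint (as a semi-automated reader would from the visible
#' compartment), which tolerates bias fields; voxels exactly at threshold
#' are included. Each slice's mask is a single connected component.
#'
#' @param stack an `mri_stack` (axial for compartment volumetry).
#' @param min_contrast minimum per-slice plateau contrast, as a fraction of
#'   the global contrast, below which a slice is declared empty (the
#'   compartment is no longer discernible there).
#' @return Logical array of the stack's shape with attribute
#'   `thresholds` (per-slice threshold, `NA` for empty slices).
#' @export
segment_compartment <- function(stack, min_contrast = 0.08) {
  stopifnot(inherits(stack, "mri_stack"))
  dat <- stack$data
  d <- dim(dat)
  gl <- tryCatch(profile_levels(as.vector(dat)),
                 error = function(e) stop("segmentation failed: ",
                                          conditionMessage(e), call. = FALSE))
  mask <- array(FALSE, d)
  thr_out <- rep(NA_real_, d[3])

  # seed: the most central slice containing the phantom, where the
  # compartment wall has full through-slice contrast
  area <- apply(dat >= gl$threshold, 3, sum)
  k0 <- central_max_slice(area)
  ctr <- cbind(round(d[1] / 2), round(d[2] / 2))
  seed_mask <- matrix(FALSE, d[1], d[2])
  seed_mask[ctr] <- TRUE

  # dilation brush bounding slice-to-slice growth (~0.2 mm): partial volume
  # can bridge the thin wall in oblique slices, so propagated components are
  # clipped to the neighbourhood of the previous slice's mask
  px <- min(stack$grid$pixel_dx, stack$grid$pixel_dy)
  brush <- EBImage::makeBrush(2 * ceiling(0.2 / px) + 1, "disc")

  slice_component <- function(sl, prev_mask, clip = TRUE) {
    # local plateau from the previous footprint tracks bias-field modulation
    # and partial-volume dimming; a slice is kept while the compartment is
    # still discernible (min_contrast of the global contrast), and the
    # effective plateau is floored at half the global one so a vanishing
    # local contrast on a boundary slice cannot admit background
    vals <- sl[prev_mask]
    plateau <- stats::median(vals)
    if (!is.finite(plateau) ||
        plateau - gl$background < min_contrast * (gl$plateau - gl$background))
      return(NULL)
    plateau <- max(plateau, gl$background + 0.5 * (gl$plateau - gl$background))
    thr <- gl$background + 0.5 * (plateau - gl$background)
    bw <- EBImage::bwlabel(sl >= thr)
    labs <- bw[prev_mask]
    labs <- labs[labs > 0]
    if (!length(labs)) return(NULL)
    lab <- as.integer(names(sort(table(labs), decreasing = TRUE))[1])
    m <- bw == lab
    if (clip) {
      allowed <- EBImage::dilate(prev_mask, brush) > 0
      m <- m & allowed
      if (!any(m)) return(NULL)
      bw2 <- EBImage::bwlabel(m)
      sizes <- tabulate(bw2)
      m <- bw2 == which.max(sizes)
    }
    list(mask = m, threshold = thr)
  }

  first <- slice_component(dat[, , k0], seed_mask, clip = FALSE)
  if (is.null(first))
    stop("segmentation failed: no compartment component found at the ",
         "central region", call. = FALSE)
  mask[, , k0] <- first$mask; thr_out[k0] <- first$threshold

  # the compartment is rotationally symmetric about the vertical axis, so
  # its through-slice extent equals its equatorial in-plane half-width:
  # slices centred beyond that bound cannot intersect it (this stops the
  # propagation from tunnelling through the dark wall into the shell when
  # slice alignment straddles the far side of the wall)
  cols_in <- which(apply(first$mask, 2, any))
  half_width <- (diff(range(cols_in)) + 1) / 2 * stack$grid$pixel_dx
  z_of <- grid_coords(stack$grid)$slice
  z_max <- half_width + 0.5 * stack$grid$slice_thickness

  for (dir in c(1L, -1L)) {
    prev <- first$mask
    k <- k0 + dir
    while (k >= 1 && k <= d[3] && abs(z_of[k] - z_of[k0]) <= z_max) {
      res <- slice_component(dat[, , k], prev)
      if (is.null(res)) break
      mask[, , k] <- res$mask; thr_out[k] <- res$threshold
      prev <- res$mask
      k <- k + dir
    }
  }
  attr(mask, "thresholds") <- thr_out
  mask
}

#' Volume from a binary mask
#'
#' Voxel counting times the voxel volume, exactly linear in the count.
#'
#' @param mask logical/0-1 array.
#' @param voxel_volume_mm3 volume of one voxel (mm^3).
#' @return Volume in mm^3.
#' @export
compute_volume <- function(mask, voxel_volume_mm3) {
  sum(mask != 0) * voxel_volume_mm3
}

#' Measure the compartment volume of a scan
#'
#' Convenience wrapper: [segment_compartment()] then [compute_volume()]
#' with the stack's voxel volume.
#'
#' @param stack an axial `mri_stack`.
#' @param scan_id identifier recorded with the measurement.
#' @return One-row data.frame measurement record (`kind = "volume"`,
#'   value in mm^3).
#' @export
measure_volume <- function(stack, scan_id = stack$preset_name) {
  g <- stack$grid
  vol <- compute_volume(segment_compartment(stack),
                        g$pixel_dx * g$pixel_dy * g$slice_thickness)
  data.frame(scan_id = scan_id, kind = "volume", direction = NA_character_,
             plane = stack$plane, encoding_role = NA_character_,
             value = vol, stringsAsFactors = FALSE)
}

# Slice with (near-)maximal above-threshold area, preferring the most
# central slice among ties: in-plane phantom area is constant across the
# interior, and only central slices intersect the compartment axis.
central_max_slice <- function(area) {
  cand <- which(area >= 0.5 * max(area))
  cand[which.min(abs(cand - (length(area) + 1) / 2))]
}
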