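# T2 of the Gd-doped phantom solution (ms), estimated from multi-echo
# relaxometry of the filled phantom; plastic, tape and air are signal voids.
T2_SOLUTION_MS <- 53.1

# 2D structural sequence presets: "a" is the shared standard protocol,
# "b"-"f" are the per-centre stroke protocols. All use a 256 x 256 matrix
# with contiguous slices (no interslice gap).
SEQUENCE_TABLE <- list(
  a = list(type = "FSE",  tr_ms = 1600, te_eff_ms = 20, averages = 2,
           echo_train = 4, bandwidth_khz = 100.0, fov_mm = 19.2,
           matrix = 256, slice_thickness_mm = 1.0),
  b = list(type = "RARE", tr_ms = 5000, te_eff_ms = 47, averages = 2,
           echo_train = 8, bandwidth_khz = 50.0, fov_mm = 25.0,
           matrix = 256, slice_thickness_mm = 0.75),
  c = list(type = "MSME", tr_ms = 3375, te_eff_ms = seq(11, 176, by = 11),
           averages = 1, echo_train = 1, bandwidth_khz = 59.5,
           fov_mm = 19.2, matrix = 256, slice_thickness_mm = 1.0),
  d = list(type = "RARE", tr_ms = 2742, te_eff_ms = 33, averages = 4,
           echo_train = 8, bandwidth_khz = 47.0, fov_mm = 40.0,
           matrix = 256, slice_thickness_mm = 1.0),
  e = list(type = "RARE", tr_ms = 3000, te_eff_ms = 24, averages = 1,
           echo_train = 4, bandwidth_khz = 50.0, fov_mm = 25.0,
           matrix = 256, slice_thickness_mm = 0.6),
  f = list(type = "RARE", tr_ms = 3500, te_eff_ms = 33, averages = 4,
           echo_train = 8, bandwidth_khz = 32.9, fov_mm = 25.6,
           matrix = 256, slice_thickness_mm = 0.5))

#' Imaging sequence presets
#'
#' Returns the acquisition parameters of one of the study's six 2D structural
#' sequences: the standard protocol `"a"` (FSE, FOV 19.2 mm, 256 x 256,
#' 1 mm slices, 100 kHz bandwidth) or a centre-specific stroke protocol
#' `"b"`-`"f"`. Preset `"c"` is a multi-slice multi-echo (MSME) sequence whose
#' `te_eff_ms` is the full echo-time list (11-176 ms) used for T2 mapping.
#'
#' @param name one of `"a"` to `"f"`.
#' @return An object of class `sequence_preset`: acquisition type, TR, TE
#'   (scalar, or echo list for `"c"`), averages, echo train length, receive
#'   bandwidth (kHz), FOV (mm), matrix size and slice thickness (mm).
#' @examples
#' sequence_preset("a")$fov_mm / sequence_preset("a")$matrix  # pixel 0.075 mm
#' @export
sequence_preset <- function(name = c("a", "b", "c", "d", "e", "f")) {
  name <- match.arg(name)
  p <- SEQUENCE_TABLE[[name]]
  p$name <- name
  structure(p, class = "sequence_preset")
}

#' @export
print.sequence_preset <- function(x, ...) {
  te <- if (length(x$te_eff_ms) > 1)
    sprintf("%g-%g ms (%d echoes)", min(x$te_eff_ms), max(x$te_eff_ms),
            length(x$te_eff_ms)) else sprintf("%g ms", x$te_eff_ms)
  cat(sprintf("sequence \"%s\" (%s): TR %g ms, TE_eff %s, FOV %g mm, %dx%d, slice %g mm, BW %g kHz\n",
              x$name, x$type, x$tr_ms, te, x$fov_mm, x$matrix, x$matrix,
              x$slice_thickness_mm, x$bandwidth_khz))
  invisible(x)
}
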