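#' Linear scaling and volumetric errors
#'
#' Percent deviation of a measurement from its ground truth:
#' `100 * (measured - truth) / truth`. `scaling_error` is for lengths (mm),
#' `volumetric_error` for volumes (mm^3); both vectorize over `measured`.
#'
#' @param measured_mm,measured_mm3 measured value(s).
#' @param truth_mm,truth_mm3 ground-truth value, strictly positive.
#' @return Error(s) in percent.
#' @export
scaling_error <- function(measured_mm, truth_mm) {
  if (any(truth_mm <= 0)) stop("ground truth must be > 0", call. = FALSE)
  100 * (measured_mm - truth_mm) / truth_mm
}

#' @rdname scaling_error
#' @export
volumetric_error <- function(measured_mm3, truth_mm3) {
  if (any(truth_mm3 <= 0)) stop("ground truth must be > 0", call. = FALSE)
  100 * (measured_mm3 - truth_mm3) / truth_mm3
}

#' Volumetric error predicted from per-direction scaling errors
#'
#' If the three orthogonal directions scale independently by
#' `(1 + e/100)`, a volume scales by their product:
#' `pe_V = 100 * (e_x + 100)(e_y + 100)(e_z + 100) / 10^6 - 100`.
#' Symmetric in its arguments and strictly increasing in each. The
#' difference between a measured volumetric error and this prediction
#' isolates non-scaling contributions (partial volume, noise, thresholding).
#'
#' @param e_x,e_y,e_z per-direction scaling errors in percent, each > -100.
#' @return Predicted volumetric error in percent.
#' @examples
#' predicted_volumetric_error(1, 1, 1)       # 3.0301
#' predicted_volumetric_error(4.47, 4.82, 4.47)
#' @export
predicted_volumetric_error <- function(e_x, e_y, e_z) {
  if (any(c(e_x, e_y, e_z) <= -100))
    stop("scaling errors must be > -100 %", call. = FALSE)
  100 * (e_x + 100) * (e_y + 100) * (e_z + 100) / 1e6 - 100
}

#' Measured-versus-predicted volumetric error difference
#'
#' Two labelled forms of the discrepancy between a measured volumetric error
#' and the prediction from linear scaling: the simple difference in error
#' points (`e_v - pe_v`) and the ratio form, the percent by which the
#' measured volume exceeds the predicted volume
#' (`100 * ((e_v + 100) / (pe_v + 100) - 1)`).
#'
#' @param e_v measured volumetric error (percent).
#' @param pe_v predicted volumetric error (percent), > -100.
#' @return List with `simple_points` and `ratio_pct`.
#' @export
measured_vs_predicted_difference <- function(e_v, pe_v) {
  if (any(pe_v <= -100)) stop("pe_v must be > -100 %", call. = FALSE)
  list(simple_points = e_v - pe_v,
       ratio_pct = 100 * ((e_v + 100) / (pe_v + 100) - 1))
}

#' Grouped median / IQR / range summaries
#'
#' Medians and quartiles use linear interpolation (R quantile type 7).
#'
#' @param values numeric vector.
#' @param groups optional data.frame / list of grouping vectors (recycled
#'   against `values`); `NULL` summarizes everything as one group.
#' @return data.frame with one row per group: `n`, `median`, `q25`, `q75`,
#'   `iqr`, `min`, `max`.
#' @export
summarize_errors <- function(values, groups = NULL) {
  if (!length(values)) stop("empty group: nothing to summarize",
                            call. = FALSE)
  if (is.null(groups)) groups <- list(group = rep("all", length(values)))
  groups <- as.data.frame(groups, stringsAsFactors = FALSE)
  if (anyNA(values)) stop("NA values in summary input", call. = FALSE)
  key <- interaction(groups, drop = TRUE, lex.order = TRUE)
  out <- do.call(rbind, lapply(split(seq_along(values), key), function(idx) {
    v <- values[idx]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    cbind(groups[idx[1], , drop = FALSE],
          data.frame(n = length(v), median = q[2], q25 = q[1], q75 = q[3],
                     iqr = q[3] - q[1], min = min(v), max = max(v)))
  }))
  rownames(out) <- NULL
  out
}

#' Mann-Whitney U test
#'
#' `U` for group A counts pairs where `a < b`, plus half of ties, so a
#' stochastically smaller group A gives a large `U_a`; both orientations are
#' reported (`U_a + U_b = n_a * n_b`). The two-sided p-value is exact (null
#' distribution of U) when there are no ties and `n_a * n_b <= 400`,
#' otherwise a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param group_a,group_b numeric vectors, non-empty.
#' @return List with `U_a`, `U_b`, `U` (the smaller), `p`, and `method`.
#' @export
mann_whitney_u <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b))
    stop("both groups must be non-empty", call. = FALSE)
  na <- length(group_a); nb <- length(group_b)
  r <- rank(c(group_a, group_b))
  ra <- sum(r[seq_len(na)])
  # rank-sum identity: sum of ranks of A = #(a > b) + ties/2 + na(na+1)/2
  U_gt <- ra - na * (na + 1) / 2          # pairs a > b (+ half ties)
  U_a <- na * nb - U_gt                   # pairs a < b (+ half ties)
  U_b <- na * nb - U_a
  Umin <- min(U_a, U_b)
  ties <- any(duplicated(c(group_a, group_b)))
  if (!ties && na * nb <= 400) {
    p <- if (U_a == U_b) 1 else 2 * stats::pwilcox(Umin, na, nb)
    p <- min(1, p)
    method <- "exact"
  } else {
    tie_tab <- table(c(group_a, group_b))
    n <- na + nb
    mu <- na * nb / 2
    sig2 <- na * nb / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sig2 <= 0) { p <- 1 }
    else {
      zz <- (abs(U_a - mu) - 0.5) / sqrt(sig2)   # continuity corrected
      p <- 2 * stats::pnorm(-max(zz, 0))
    }
    p <- min(1, p)
    method <- "normal_tie_corrected"
  }
  list(U_a = U_a, U_b = U_b, U = Umin, p = p, method = method)
}

#' Bland-Altman agreement analysis
#'
#' Mean paired difference (accuracy) and 95 % limits of agreement
#' (mean +/- 1.96 SD of the differences, SD with n-1 denominator).
#'
#' @param values_a,values_b equal-length paired numeric vectors, n >= 2.
#' @return List with `mean_diff`, `sd_diff`, `loa` (lower, upper) and the
#'   per-pair `differences`.
#' @export
bland_altman <- function(values_a, values_b) {
  if (length(values_a) != length(values_b))
    stop("paired vectors must have equal length", call. = FALSE)
  if (length(values_a) < 2) stop("need n >= 2 pairs", call. = FALSE)
  d <- values_a - values_b
  m <- mean(d); s <- stats::sd(d)
  list(mean_diff = m, sd_diff = s,
       loa = c(lower = m - 1.96 * s, upper = m + 1.96 * s),
       differences = d)
}

#' Dice overlap coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)` between two same-shaped binary masks;
#' two empty masks are defined to overlap perfectly (with a warning).
#'
#' @param mask_a,mask_b logical/0-1 arrays of identical shape.
#' @return Coefficient in `[0, 1]`.
#' @export
dice <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b)) ||
      length(mask_a) != length(mask_b))
    stop("mask shapes differ", call. = FALSE)
  a <- mask_a != 0; b <- mask_b != 0
  denom <- sum(a) + sum(b)
  if (denom == 0) {
    warning("both masks empty: Dice defined as 1", call. = FALSE)
    return(1)
  }
  2 * sum(a & b) / denom
}
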