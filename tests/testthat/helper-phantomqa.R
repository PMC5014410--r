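# Shared fixtures; expensive simulations are cached across test files.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

default_spec <- phantom_spec()

analytic_volume <- function(spec = default_spec) {
  frustum_volume(spec$frustum_r_top, spec$frustum_r_bottom,
                 spec$frustum_height)
}

truth_dims <- c(x = 12.80, y = 8.45, z = 12.80)

# noiseless 3-slice scans reused by several tests
axial_scan <- function() cached("axial3",
  simulate_scan(default_spec, "a", "axial", n_slices = 3))
coronal_scan <- function() cached("coronal3",
  simulate_scan(default_spec, "a", "coronal", n_slices = 3))

# step profile with 50 %-threshold crossings at the given fractional
# 1-based sample positions (background 0, plateau 1)
step_profile <- function(n = 121, left = 10.25, right = 110.75) {
  p <- numeric(n)
  il <- floor(left); fl <- left - il
  ir <- floor(right); fr <- right - ir
  # choose straddling samples so that linear interpolation at 0.5 hits the
  # requested positions: p[il] < 0.5 < p[il + 1]
  p[(il + 2):(ir - 1)] <- 1
  p[il] <- 0.4
  p[il + 1] <- 0.4 + 0.1 / fl            # 0.5 crossing at il + fl
  p[ir + 1] <- 0.4
  p[ir] <- 0.4 + 0.1 / (1 - fr)          # 0.5 crossing at ir + fr
  p
}

# percent scaling errors recovered from one axial + one coronal scan
recover_scaling <- function(distortion, noise = NULL, n_slices = 3,
                            planes = c("axial", "coronal")) {
  recs <- do.call(rbind, lapply(planes, function(pl)
    measure_dimensions(simulate_scan(default_spec, "a", pl,
                                     distortion = distortion, noise = noise,
                                     n_slices = n_slices))))
  err <- scaling_error(recs$value, truth_dims[recs$direction])
  data.frame(direction = recs$direction, error_pct = err)
}

# exhaustive pair-counting Mann-Whitney oracle
brute_force_u <- function(a, b) {
  lt <- sum(outer(a, b, `<`))
  eq <- sum(outer(a, b, `==`))
  lt + eq / 2
}
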