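# Shared fixture builders; everything is generated in code.

# small square scene for fast simulator tests
small_scene <- function(n = 24, irrigation = 10, ...) {
  scene_preset("calyx", grid_shape = c(n, n), tissue_thickness_mm = 4,
               irrigation_ml_per_min = irrigation, ...)
}

# acquisition matched to a scene grid (square-ish FOV, default timing)
acq_for_scene <- function(scene, ...) {
  acquisition_params(fov_mm = scene$grid_shape * scene$pixel_mm,
                     matrix_size = scene$grid_shape, ...)
}

# uniform-magnitude dynamic series from a raw phase stack
series_from_phase <- function(phase, acq = NULL, baseline_frames = 1L,
                              magnitude = 100) {
  d <- dim(phase)
  if (is.null(acq))
    acq <- acquisition_params(matrix_size = d[1:2],
                              fov_mm = as.numeric(d[1:2]))
  dynamic_series(array(magnitude, d), phase,
                 times_s = (seq_len(d[3]) - 1) * acq$frame_interval_s,
                 acq = acq, baseline_frame_count = baseline_frames)
}

# full-keep mask for a given shape
full_mask <- function(shape) pixel_mask(matrix(TRUE, shape[1], shape[2]))

# scalar per-pixel, per-frame CEM43 oracle: plain double loop, independent
# of the vectorized implementation
cem43_oracle <- function(delta_t, keep, baseline, dt_s, params) {
  d <- dim(delta_t)
  dose <- matrix(0, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    if (!keep[i, j]) next
    acc <- 0
    for (k in seq_len(d[3])) {
      temp <- baseline + delta_t[i, j, k]
      if (temp < params$t_floor_C) next
      r <- if (temp >= params$t_break_C) params$r_above else params$r_below
      acc <- acc + (dt_s / 60) * r^(params$t_break_C - temp)
    }
    dose[i, j] <- acc
  }
  dose
}

# brute-force mask-aware box mean oracle (double loop over neighbourhoods)
box_mean_oracle <- function(frame, keep, width) {
  half <- (width - 1) %/% 2
  out <- frame
  nr <- nrow(frame); nc <- ncol(frame)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!keep[i, j]) next
    rs <- max(1, i - half):min(nr, i + half)
    cs <- max(1, j - half):min(nc, j + half)
    vals <- frame[rs, cs, drop = FALSE]
    sel <- keep[rs, cs, drop = FALSE]
    out[i, j] <- mean(vals[sel])
  }
  out
}

# the PRF phase-per-degree factor, written out independently of the package
prf_factor_oracle <- function(b0, te, coeff_ppm) {
  2 * pi * 42.577e6 * b0 * coeff_ppm * 1e-6 * te
}
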