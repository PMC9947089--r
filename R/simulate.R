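#' Ground-truth temperature series
#'
#' Time-ordered rasters of absolute temperature with frame timestamps and
#' the per-frame laser state. Produced by [simulate_temperature()]; consumed
#' by [encode_mr_series()] and by parameter-recovery tests.
#'
#' @param frames 3D numeric array `(rows, cols, frames)`, degrees C.
#' @param times_s Numeric vector of frame timestamps, seconds, strictly
#'   increasing.
#' @param laser_on Logical vector, laser state at each frame time.
#' @param baseline_temp_C Baseline (bath) temperature, degrees C.
#' @param floor_temp_C Coldest admissible temperature in the scene (the
#'   irrigant temperature); frames are validated against it.
#' @return An object of class `ground_truth_series`.
#' @export
ground_truth_series <- function(frames, times_s, laser_on, baseline_temp_C,
                                floor_temp_C = baseline_temp_C - 5) {
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  n <- dim(frames)[3]
  if (length(times_s) != n || length(laser_on) != n)
    stop("times_s and laser_on must match the number of frames", call. = FALSE)
  if (n > 1 && any(diff(times_s) <= 0))
    stop("times_s must be strictly increasing", call. = FALSE)
  if (any(frames < floor_temp_C - 1e-9))
    stop("frames fall below the physical floor temperature", call. = FALSE)
  structure(
    list(frames = frames, times_s = as.numeric(times_s),
         laser_on = as.logical(laser_on),
         baseline_temp_C = baseline_temp_C),
    class = "ground_truth_series")
}

#' @export
print.ground_truth_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "Ground-truth series: %d frames of %d x %d, t = [%.2f, %.2f] s, peak %.1f C\n",
    d[3], d[1], d[2], x$times_s[1], x$times_s[length(x$times_s)],
    max(x$frames)))
  invisible(x)
}

# 5-point Laplacian with zero-flux (replicated-edge) boundaries, 1/mm^2
laplacian_2d <- function(t_mat, pixel_mm) {
  nr <- nrow(t_mat); nc <- ncol(t_mat)
  up    <- t_mat[c(1, seq_len(nr - 1)), , drop = FALSE]
  down  <- t_mat[c(seq_len(nr - 1) + 1, nr), , drop = FALSE]
  left  <- t_mat[, c(1, seq_len(nc - 1)), drop = FALSE]
  right <- t_mat[, c(seq_len(nc - 1) + 1, nc), drop = FALSE]
  (up + down - 2 * t_mat) / pixel_mm[1]^2 +
    (left + right - 2 * t_mat) / pixel_mm[2]^2
}

# Gaussian source raster, peak 1 at the fiber tip
source_profile <- function(scene) {
  gs <- scene$grid_shape
  rows <- matrix(seq_len(gs[1]), gs[1], gs[2])
  cols <- matrix(seq_len(gs[2]), gs[1], gs[2], byrow = TRUE)
  d2 <- ((rows - scene$source_position[1]) * scene$pixel_mm[1])^2 +
        ((cols - scene$source_position[2]) * scene$pixel_mm[2])^2
  exp(-d2 / (2 * scene$source_sigma_mm^2))
}

#' Simulate pulsed-laser heating of a renal cavity
#'
#' Explicit finite-difference integration of a 2D heat equation with a
#' pulsed Gaussian source at the fiber tip and Newtonian sink terms:
#' \deqn{\partial T/\partial t = D \nabla^2 T + s(r)\,A\,[\mathrm{on}(t)]
#'   - k_I I (T - T_{irr}) \,[\mathrm{cavity}]
#'   - k_t (T - T_0) \,[\mathrm{tissue}]}
#' Bath pixels (outside both masks) are clamped at the baseline temperature.
#' The temperature field is sampled every `frame_interval_s` seconds,
#' emulating the dynamic MR acquisition. The run is fully deterministic.
#'
#' @param protocol A [laser_protocol()]. The source amplitude scales
#'   linearly with `protocol$power_watts` (see [thermal_scene()]).
#' @param scene A [thermal_scene()].
#' @param duration_s Total simulated time, seconds; must cover the
#'   protocol's on+off train plus `laser_start_s`.
#' @param frame_interval_s Sampling interval of the output frames (TA),
#'   seconds.
#' @param laser_start_s Pre-heating delay before the first application,
#'   seconds; the leading frames provide the thermometry baseline.
#' @param burn_in_s Irrigation-on, laser-off settling time integrated before
#'   the first frame, seconds. Emulates the pre-experiment rinsing that
#'   homogenizes the temperature field, so the baseline frames show the
#'   steady pre-laser state rather than an irrigation transient.
#' @return A [ground_truth_series()].
#' @examples
#' sc <- scene_preset("calyx", irrigation_ml_per_min = 10)
#' pr <- laser_protocol(30, 5, 5, n_applications = 2)
#' gt <- simulate_temperature(pr, sc, duration_s = 30)
#' max(gt$frames) > 43   # cavity heats past the dose breakpoint
#' @export
simulate_temperature <- function(protocol, scene, duration_s,
                                 frame_interval_s = 0.62,
                                 laser_start_s = 5, burn_in_s = 60) {
  stopifnot(inherits(protocol, "laser_protocol"),
            inherits(scene, "thermal_scene"))
  if (duration_s < protocol_duration(protocol))
    stop("duration_s must cover the protocol's total on+off time",
         call. = FALSE)

  dt <- scene$sim_dt_s
  amp <- scene$source_amplitude_K_per_s *
    protocol$power_watts / scene$calibration_power_W
  src <- source_profile(scene) * amp
  cavity <- scene$cavity_mask
  tissue <- scene$tissue_mask
  bath <- !(cavity | tissue)
  k_cav <- scene$cooling_coeff_per_ml * scene$irrigation_ml_per_min
  k_tis <- scene$tissue_cooling_per_s
  t0 <- scene$baseline_temp_C
  t_irr <- scene$irrigant_temp_C

  frame_times <- seq(0, duration_s, by = frame_interval_s)
  n_frames <- length(frame_times)
  frames <- array(NA_real_, c(scene$grid_shape, n_frames))

  temp <- matrix(t0, scene$grid_shape[1], scene$grid_shape[2])
  # settle to the irrigation-on steady state before the acquisition starts
  if (burn_in_s > 0) {
    for (step in seq_len(ceiling(burn_in_s / dt))) {
      rate <- scene$diffusivity_mm2_per_s * laplacian_2d(temp, scene$pixel_mm)
      rate <- rate - k_cav * (temp - t_irr) * cavity -
        k_tis * (temp - t0) * tissue
      temp <- temp + dt * rate
      temp[bath] <- t0
    }
  }
  frames[, , 1] <- temp
  next_frame <- 2L
  n_steps <- ceiling(duration_s / dt)
  for (step in seq_len(n_steps)) {
    t_now <- (step - 1) * dt
    on <- laser_on_at(protocol, t_now, start_s = laser_start_s)
    rate <- scene$diffusivity_mm2_per_s * laplacian_2d(temp, scene$pixel_mm)
    if (on) rate <- rate + src
    rate <- rate - k_cav * (temp - t_irr) * cavity -
      k_tis * (temp - t0) * tissue
    temp <- temp + dt * rate
    temp[bath] <- t0
    t_next <- step * dt
    while (next_frame <= n_frames &&
           frame_times[next_frame] <= t_next + 1e-9) {
      frames[, , next_frame] <- temp
      next_frame <- next_frame + 1L
    }
  }
  ground_truth_series(
    frames = frames, times_s = frame_times,
    laser_on = laser_on_at(protocol, frame_times, start_s = laser_start_s),
    baseline_temp_C = t0,
    floor_temp_C = min(t0, t_irr))
}
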