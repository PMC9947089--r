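#' Dynamic MR series (magnitude + phase)
#'
#' The pipeline's raw input: time-ordered magnitude and phase rasters from a
#' dynamic gradient-echo acquisition, with timestamps, acquisition metadata
#' and the number of pre-heating baseline frames.
#'
#' @param magnitude_frames 3D array `(rows, cols, frames)`, non-negative.
#' @param phase_frames 3D array of the same dim, radians in `[-pi, pi)`.
#' @param times_s Frame timestamps, seconds.
#' @param acq An [acquisition_params()].
#' @param baseline_frame_count Number of leading pre-heating frames used as
#'   the phase reference (>= 1).
#' @return An object of class `dynamic_series`.
#' @export
dynamic_series <- function(magnitude_frames, phase_frames, times_s, acq,
                           baseline_frame_count = 5L) {
  stopifnot(is.array(magnitude_frames), is.array(phase_frames),
            inherits(acq, "acquisition_params"))
  if (!identical(dim(magnitude_frames), dim(phase_frames)))
    stop("magnitude and phase frames must share one shape", call. = FALSE)
  n <- dim(magnitude_frames)[3]
  if (length(times_s) != n)
    stop("times_s must have one entry per frame", call. = FALSE)
  baseline_frame_count <- as.integer(baseline_frame_count)
  if (baseline_frame_count < 1L || baseline_frame_count >= n)
    stop("need 1 <= baseline_frame_count < number of frames", call. = FALSE)
  if (any(magnitude_frames < 0))
    stop("magnitude must be non-negative", call. = FALSE)
  rng <- range(phase_frames)
  if (rng[1] < -pi - 1e-9 || rng[2] >= pi + 1e-9)
    stop("phase must lie in [-pi, pi)", call. = FALSE)
  structure(
    list(magnitude_frames = magnitude_frames, phase_frames = phase_frames,
         times_s = as.numeric(times_s), acq = acq,
         baseline_frame_count = baseline_frame_count),
    class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  d <- dim(x$magnitude_frames)
  cat(sprintf("Dynamic MR series: %d frames of %d x %d (%d baseline)\n",
              d[3], d[1], d[2], x$baseline_frame_count))
  invisible(x)
}

#' Per-frame temperature-difference maps
#'
#' @param delta_t_frames 3D array `(rows, cols, frames)` of temperature
#'   difference from baseline, degrees C.
#' @param times_s Frame timestamps, seconds.
#' @param baseline_temp_C Absolute reference temperature, degrees C.
#' @return An object of class `temperature_series`.
#' @export
temperature_series <- function(delta_t_frames, times_s, baseline_temp_C = 37) {
  stopifnot(is.array(delta_t_frames), length(dim(delta_t_frames)) == 3)
  if (length(times_s) != dim(delta_t_frames)[3])
    stop("times_s must have one entry per frame", call. = FALSE)
  structure(
    list(delta_t_frames = delta_t_frames, times_s = as.numeric(times_s),
         baseline_temp_C = baseline_temp_C),
    class = "temperature_series")
}

#' @export
print.temperature_series <- function(x, ...) {
  d <- dim(x$delta_t_frames)
  cat(sprintf(
    "Temperature series: %d frames of %d x %d, max dT = %.2f C (baseline %.1f C)\n",
    d[3], d[1], d[2], max(x$delta_t_frames), x$baseline_temp_C))
  invisible(x)
}

# wrap into (-pi, pi]: pi maps to pi, values just above pi wrap negative
wrap_phase <- function(x) pi - ((pi - x) %% (2 * pi))

#' Temporal phase unwrapping
#'
#' Removes 2*pi wrap seams along the time axis: frame-to-frame increments
#' are mapped into `(-pi, pi]` and cumulatively summed per pixel, the first
#' frame is kept unchanged. Exact whenever the true per-frame phase step is
#' strictly inside `(-pi, pi]` — at 620 ms per frame the per-step phase
#' change from heating is far below that.
#'
#' @param phase_stack 3D array `(rows, cols, frames)` of phase, radians.
#' @return Array of the same dim with unwrapped phase.
#' @examples
#' ph <- array(c(0, 3.0), c(1, 1, 2))
#' unwrap_temporal(ph)[1, 1, 2]   # 3.0: step inside (-pi, pi]
#' @export
unwrap_temporal <- function(phase_stack) {
  stopifnot(is.array(phase_stack), length(dim(phase_stack)) == 3)
  n <- dim(phase_stack)[3]
  if (n < 2) stop("need at least 2 frames", call. = FALSE)
  out <- phase_stack
  for (k in 2:n) {
    step <- wrap_phase(phase_stack[, , k] - phase_stack[, , k - 1])
    out[, , k] <- out[, , k - 1] + step
  }
  out
}

# phase-to-temperature conversion factor, rad per degree C
prf_rad_per_C <- function(acq, prf_coeff_ppm_per_C) {
  2 * pi * GAMMA_HZ_PER_T * acq$b0_tesla * prf_coeff_ppm_per_C * 1e-6 *
    acq$te_s
}

#' Reconstruct temperature change by the PRF phase-difference method
#'
#' The proton resonance frequency of water shifts by about -0.01 ppm per
#' degree C, so heating changes the phase of a gradient-echo image by
#' `2*pi * gamma * B0 * alpha * 1e-6 * dT * TE`. The reconstruction takes
#' the circular mean of the first `baseline_frame_count` phase frames as the
#' reference, forms the pixelwise phase difference through the complex
#' product `z_t * conj(z_ref)` (avoiding wrap seams at +/-pi), unwraps it
#' along time, and divides by the PRF factor. With the negative coefficient,
#' heating yields positive temperature change.
#'
#' @param series A [dynamic_series()].
#' @param prf_coeff_ppm_per_C PRF thermal coefficient, ppm per degree C
#'   (default [PRF_COEFF_DEFAULT]).
#' @param baseline_temp_C Absolute baseline temperature attached to the
#'   result, degrees C.
#' @return A [temperature_series()] of per-frame temperature differences.
#' @examples
#' # a one-pixel series whose phase drops 0.602 rad after the baseline
#' acq <- acquisition_params(matrix_size = c(8, 8), fov_mm = c(8, 8))
#' ph <- array(0, c(8, 8, 3)); ph[, , 3] <- -0.602
#' mg <- array(100, c(8, 8, 3))
#' ds <- dynamic_series(mg, ph, times_s = 0:2, acq, baseline_frame_count = 2)
#' ts <- reconstruct_delta_t(ds)
#' ts$delta_t_frames[1, 1, 3]   # about +10 degrees C
#' @export
reconstruct_delta_t <- function(series, prf_coeff_ppm_per_C = PRF_COEFF_DEFAULT,
                                baseline_temp_C = 37) {
  stopifnot(inherits(series, "dynamic_series"))
  acq <- series$acq
  if (acq$te_s <= 0 || acq$b0_tesla <= 0)
    stop("TE and B0 must be positive for PRF reconstruction", call. = FALSE)
  if (prf_coeff_ppm_per_C == 0)
    stop("prf_coeff_ppm_per_C must be non-zero", call. = FALSE)

  nb <- series$baseline_frame_count
  ph <- series$phase_frames
  # circular mean of the baseline phase frames
  zb <- matrix(0 + 0i, dim(ph)[1], dim(ph)[2])
  for (k in seq_len(nb)) zb <- zb + exp(1i * ph[, , k])
  phi_base <- Arg(zb)

  n <- dim(ph)[3]
  dphi <- array(0, dim(ph))
  for (k in seq_len(n))
    dphi[, , k] <- Arg(exp(1i * (ph[, , k] - phi_base)))
  dphi <- unwrap_temporal(dphi)

  if (any(!is.finite(dphi)))
    stop("non-finite phase encountered during reconstruction", call. = FALSE)
  delta_t <- dphi / prf_rad_per_C(acq, prf_coeff_ppm_per_C)
  temperature_series(delta_t, series$times_s, baseline_temp_C)
}
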