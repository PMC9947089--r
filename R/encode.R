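#' Encode a ground-truth temperature series into a noisy dynamic MR series
#'
#' Forward PRF model: each pixel's complex signal is
#' `M * exp(i * (phi0 + 2*pi * gamma * B0 * alpha * 1e-6 * dT * TE))`
#' where `dT` is the temperature difference from baseline and `alpha` the
#' PRF coefficient in ppm per degree C. The magnitude `M` is a uniform
#' object signal level, except in an air border of `air_margin_px` pixels
#' around the frame where it is (near) zero — this border provides the
#' air reference for the magnitude noise filter. Independent Gaussian noise
#' of standard deviation `noise_sd` is added to the real and imaginary
#' channels; the output magnitude/phase are the modulus and argument of the
#' noisy complex signal. Bit-for-bit reproducible for a fixed seed.
#'
#' @param truth A [ground_truth_series()]; its raster shape must equal
#'   `acq$matrix_size`.
#' @param acq An [acquisition_params()].
#' @param prf_coeff_ppm_per_C PRF coefficient, ppm per degree C.
#' @param noise_sd Standard deviation of the complex Gaussian noise in
#'   signal units (>= 0).
#' @param air_margin_px Width of the near-zero-signal air border, pixels.
#' @param seed Integer seed for the noise generator; one generator per call.
#' @param signal_level Object magnitude in arbitrary units.
#' @param baseline_phase Spatially constant receiver phase of the baseline,
#'   radians.
#' @return A [dynamic_series()] whose `baseline_frame_count` is the number
#'   of leading frames acquired before the first laser application (at
#'   least 1).
#' @examples
#' sc <- scene_preset("calyx", grid_shape = c(16, 16))
#' acq <- acquisition_params(matrix_size = c(16, 16), fov_mm = c(21.6, 21.6))
#' gt <- simulate_temperature(laser_protocol(30, 5, 5, 1), sc, 15)
#' ds <- encode_mr_series(gt, acq, noise_sd = 0, seed = 1)
#' @export
encode_mr_series <- function(truth, acq,
                             prf_coeff_ppm_per_C = PRF_COEFF_DEFAULT,
                             noise_sd = 2, air_margin_px = 4L, seed = 1L,
                             signal_level = 100, baseline_phase = 0.3) {
  stopifnot(inherits(truth, "ground_truth_series"),
            inherits(acq, "acquisition_params"))
  d <- dim(truth$frames)
  if (!identical(as.integer(d[1:2]), acq$matrix_size))
    stop("truth frame shape must match the acquisition matrix", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (any(!is.finite(truth$frames)))
    stop("non-finite temperatures in ground truth", call. = FALSE)

  k_rad_per_C <- prf_rad_per_C(acq, prf_coeff_ppm_per_C)
  mag0 <- matrix(signal_level, d[1], d[2])
  m <- as.integer(air_margin_px)
  if (m > 0) {
    border <- matrix(FALSE, d[1], d[2])
    border[c(seq_len(m), d[1] - seq_len(m) + 1L), ] <- TRUE
    border[, c(seq_len(m), d[2] - seq_len(m) + 1L)] <- TRUE
    mag0[border] <- 0
  }

  n <- d[3]
  magnitude <- array(NA_real_, d)
  phase <- array(NA_real_, d)
  withr::with_seed(as.integer(seed), {
    for (k in seq_len(n)) {
      dt_map <- truth$frames[, , k] - truth$baseline_temp_C
      z <- mag0 * exp(1i * (baseline_phase + k_rad_per_C * dt_map))
      if (noise_sd > 0)
        z <- z + complex(real = stats::rnorm(length(z), 0, noise_sd),
                         imaginary = stats::rnorm(length(z), 0, noise_sd))
      magnitude[, , k] <- Mod(z)
      # Arg() returns (-pi, pi]; store per the [-pi, pi) raster convention
      p <- Arg(z)
      p[p >= pi] <- -pi
      phase[, , k] <- p
    }
  })

  n_baseline <- sum(cumprod(!truth$laser_on))
  dynamic_series(magnitude, phase, truth$times_s, acq,
                 baseline_frame_count = max(1L, min(n_baseline, n - 1L)))
}
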