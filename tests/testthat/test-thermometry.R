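test_that("temporal unwrapping leaves constant stacks unchanged", {
  ph <- array(stats::runif(4 * 4 * 6, -3, 3)[rep(1:16, 6)], c(4, 4, 6))
  expect_equal(unwrap_temporal(ph), ph)
})

test_that("sub-pi increments accumulate without wrapping", {
  # +0.5 rad per frame over 20 frames from 0: final value 9.5 rad
  ph_true <- array(rep(seq(0, by = 0.5, length.out = 20), each = 1),
                   c(1, 1, 20))
  wrapped <- Arg(exp(1i * ph_true))
  out <- unwrap_temporal(wrapped)
  expect_equal(out[1, 1, 20], 9.5, tolerance = 1e-12)
})

test_that("steps beyond +pi wrap to the equivalent negative step", {
  ph <- array(c(0, 3.2), c(1, 1, 2))
  out <- unwrap_temporal(ph)
  expect_equal(out[1, 1, 2], 3.2 - 2 * pi, tolerance = 1e-12)
  # brute-force check over a grid of step sizes: the unwrapped step is the
  # representative of the true step modulo 2*pi lying in (-pi, pi]
  for (step in seq(-6, 6, by = 0.37)) {
    o <- unwrap_temporal(array(c(0.2, 0.2 + step), c(1, 1, 2)))
    got <- o[1, 1, 2] - 0.2
    cand <- step + 2 * pi * (-3:3)
    expected <- cand[cand > -pi - 1e-12 & cand <= pi + 1e-12][1]
    expect_equal(got, expected, tolerance = 1e-9)
  }
})

test_that("identical phase in all frames reconstructs to zero temperature", {
  ph <- array(0.7, c(8, 8, 5))
  ds <- series_from_phase(ph, baseline_frames = 2)
  ts <- reconstruct_delta_t(ds)
  expect_true(all(abs(ts$delta_t_frames) < 1e-12))
})

test_that("a -0.602 rad phase drop maps to +10 C at 1.5 T, TE 15 ms", {
  ph <- array(0, c(8, 8, 3))
  ph[3, 5, 3] <- prf_factor_oracle(1.5, 0.015, -0.01) * 10
  acq <- acquisition_params(matrix_size = c(8, 8), fov_mm = c(11, 11))
  ds <- series_from_phase(ph, acq, baseline_frames = 2)
  ts <- reconstruct_delta_t(ds, prf_coeff_ppm_per_C = -0.01)
  expect_equal(ts$delta_t_frames[3, 5, 3], 10, tolerance = 1e-9)
  expect_equal(ts$delta_t_frames[1, 1, 3], 0, tolerance = 1e-12)
})

test_that("reconstruction is linear in the phase difference", {
  ph1 <- array(0, c(8, 8, 3)); ph1[2, 2, 3] <- -0.2
  ph2 <- ph1; ph2[2, 2, 3] <- -0.4
  t1 <- reconstruct_delta_t(series_from_phase(ph1))$delta_t_frames[2, 2, 3]
  t2 <- reconstruct_delta_t(series_from_phase(ph2))$delta_t_frames[2, 2, 3]
  expect_equal(t2, 2 * t1, tolerance = 1e-12)
})

test_that("noiseless encode -> reconstruct recovers the ground truth", {
  sc <- small_scene(24, irrigation = 10)
  gt <- simulate_temperature(laser_protocol(30, 5, 5, 2), sc, 30)
  acq <- acq_for_scene(sc)
  ds <- encode_mr_series(gt, acq, noise_sd = 0, air_margin_px = 0, seed = 1)
  ts <- reconstruct_delta_t(ds, baseline_temp_C = sc$baseline_temp_C)
  # truth dT relative to the same reference the reconstruction uses: the
  # mean of the pre-laser baseline frames
  nb <- ds$baseline_frame_count
  ref <- apply(gt$frames[, , seq_len(nb), drop = FALSE], c(1, 2), mean)
  truth_dt <- sweep(gt$frames, c(1, 2), ref)
  expect_lt(max(abs(ts$delta_t_frames - truth_dt)), 1e-6)
})

test_that("random sub-pi phase trajectories reconstruct exactly", {
  acq <- acquisition_params(matrix_size = c(8, 8), fov_mm = c(11, 11))
  k_fac <- prf_factor_oracle(acq$b0_tesla, acq$te_s, -0.01)
  for (seed in 1:5) {
    withr::with_seed(seed, {
      steps <- array(stats::runif(8 * 8 * 11, -3, 3), c(8, 8, 11))
    })
    steps[, , 1] <- 0
    true_phase <- apply(steps, c(1, 2), cumsum)          # frames x r x c
    true_phase <- aperm(true_phase, c(2, 3, 1))
    wrapped <- Arg(exp(1i * true_phase))
    wrapped[wrapped >= pi] <- -pi
    ds <- series_from_phase(wrapped, acq, baseline_frames = 1)
    ts <- reconstruct_delta_t(ds, prf_coeff_ppm_per_C = -0.01)
    expect_equal(ts$delta_t_frames, true_phase / k_fac, tolerance = 1e-9)
  }
})

test_that("reconstruction error scales with the noise-to-signal ratio", {
  sc <- small_scene(24)
  frames <- array(sc$baseline_temp_C, c(24, 24, 30))
  gt <- ground_truth_series(frames, 0.62 * (0:29), rep(FALSE, 30),
                            sc$baseline_temp_C)
  acq <- acq_for_scene(sc)
  k_fac <- abs(prf_factor_oracle(acq$b0_tesla, acq$te_s, -0.01))
  rms_at <- function(noise_sd, seed) {
    ds <- encode_mr_series(gt, acq, noise_sd = noise_sd, air_margin_px = 0,
                           seed = seed, signal_level = 100)
    ts <- reconstruct_delta_t(ds)
    post <- ts$delta_t_frames[, , 6:30]   # frames beyond the baseline set
    sqrt(mean(post^2))
  }
  for (noise_sd in c(1, 3)) {
    rms <- mean(vapply(1:4, function(s) rms_at(noise_sd, s), numeric(1)))
    theory <- (noise_sd / 100) / k_fac
    expect_lt(rms, 3 * theory)
    expect_gt(rms, theory / 3)
  }
})

test_that("degenerate inputs are rejected", {
  ph <- array(0, c(8, 8, 3))
  expect_error(series_from_phase(ph, baseline_frames = 3),
               "baseline_frame_count")
  ds <- series_from_phase(ph, baseline_frames = 1)
  expect_error(reconstruct_delta_t(ds, prf_coeff_ppm_per_C = 0), "non-zero")
})
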