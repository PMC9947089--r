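test_that("a uniform image below threshold is removed entirely", {
  mag <- array(10, c(6, 6, 3))
  air <- border_roi(c(6, 6), 1)
  mk <- noise_mask(mag, air, factor = 3.7)   # 10 < 3.7 * 10
  expect_equal(mk$n_kept, 0)
})

test_that("a bright object over a dim air floor is fully kept", {
  mag <- array(100, c(8, 8, 2))
  mag[1, , ] <- 1; mag[8, , ] <- 1; mag[, 1, ] <- 1; mag[, 8, ] <- 1
  air <- roi_spec(matrix(c(TRUE, rep(FALSE, 63)), 8, 8))  # corner air pixel
  mk <- noise_mask(mag, air, factor = 3.7)
  expect_true(all(mk$keep[2:7, 2:7]))
  expect_false(any(mk$keep[1, ]))
})

test_that("kept counts match an exhaustive pixel scan", {
  for (seed in 1:4) {
    withr::with_seed(seed, {
      mag <- array(stats::runif(12 * 12 * 3, 0, 50), c(12, 12, 3))
    })
    air <- border_roi(c(12, 12), 2)
    factor <- 2.5
    mk <- noise_mask(mag, air, factor)
    mean_mag <- apply(mag, c(1, 2), mean)
    s_air <- mean(mean_mag[rasterize_roi(air, c(12, 12))])
    brute <- 0L
    for (i in 1:12) for (j in 1:12)
      if (mean_mag[i, j] >= factor * s_air) brute <- brute + 1L
    expect_equal(mk$n_kept, brute)
    expect_equal(mk$provenance$noise$removed, 144L - brute)
  }
})

test_that("an empty air ROI is a usage error", {
  mag <- array(1, c(6, 6, 2))
  expect_error(noise_mask(mag, roi_spec(matrix(FALSE, 6, 6))), "empty")
})

test_that("a full-frame ROI leaves the mask unchanged; a disjoint one empties it", {
  keep <- matrix(TRUE, 6, 6); keep[1, ] <- FALSE
  mk <- pixel_mask(keep)
  full <- roi_spec(matrix(TRUE, 6, 6))
  expect_equal(apply_roi(mk, full)$keep, keep)
  none <- roi_spec(matrix(FALSE, 6, 6))
  expect_equal(apply_roi(mk, none)$n_kept, 0)
})

test_that("a unit square around one pixel centre keeps exactly that pixel", {
  mk <- full_mask(c(9, 9))
  poly <- roi_spec(rbind(c(4.5, 5.5), c(4.5, 6.5), c(5.5, 6.5), c(5.5, 5.5)))
  out <- apply_roi(mk, poly)
  expect_equal(out$n_kept, 1)
  expect_true(out$keep[5, 6])
})

test_that("polygon rasterization agrees with an independent point-in-polygon oracle", {
  skip_if_not_installed("mgcv")
  for (seed in 1:5) {
    verts <- withr::with_seed(seed, {
      n <- sample(3:7, 1)
      ang <- sort(stats::runif(n, 0, 2 * pi))
      rad <- stats::runif(n, 2, 7)
      cbind(8 + rad * sin(ang), 8 + rad * cos(ang))
    })
    got <- rasterize_roi(roi_spec(verts), c(16, 16))
    pts <- cbind(rep(1:16, 16), rep(1:16, each = 16))      # (row, col) centres
    oracle <- matrix(mgcv::in.out(rbind(verts, verts[1, ]),
                                  pts), 16, 16)
    expect_equal(got, oracle)
  }
})

test_that("degenerate polygons are rejected", {
  mk <- full_mask(c(6, 6))
  line <- roi_spec(rbind(c(1, 1), c(2, 2), c(3, 3)))
  expect_error(apply_roi(mk, line), "degenerate")
})

test_that("applying an ROI is idempotent and masking is monotone", {
  withr::with_seed(7, {
    keep <- matrix(stats::runif(64) > 0.3, 8, 8)
    roi <- matrix(stats::runif(64) > 0.4, 8, 8)
  })
  mk <- pixel_mask(keep)
  once <- apply_roi(mk, roi_spec(roi))
  twice <- apply_roi(once, roi_spec(roi))
  expect_equal(once$keep, twice$keep)
  expect_lte(once$n_kept, mk$n_kept)
})

test_that("smoothing leaves constant fields unchanged", {
  ts <- temperature_series(array(3.5, c(7, 7, 4)), 0:3)
  out <- smooth_temperature(ts, full_mask(c(7, 7)))
  expect_equal(out$delta_t_frames, ts$delta_t_frames)
})

test_that("an isolated kept pixel keeps its value", {
  keep <- matrix(FALSE, 5, 5); keep[3, 3] <- TRUE
  arr <- array(stats::rnorm(25 * 2), c(5, 5, 2))
  ts <- temperature_series(arr, 0:1)
  out <- smooth_temperature(ts, pixel_mask(keep))
  expect_equal(out$delta_t_frames[3, 3, ], arr[3, 3, ])
})

test_that("smoothing matches the brute-force neighbourhood mean", {
  for (seed in 1:4) {
    withr::with_seed(seed, {
      arr <- array(stats::rnorm(8 * 8), c(8, 8, 1))
      keep <- matrix(stats::runif(64) > 0.25, 8, 8)
    })
    ts <- temperature_series(arr, 0)
    got <- smooth_temperature(ts, pixel_mask(keep))$delta_t_frames[, , 1]
    want <- box_mean_oracle(arr[, , 1], keep, 3)
    expect_equal(got, want, tolerance = 1e-12)
    # full mask, the classic case
    got_full <- smooth_temperature(ts, full_mask(c(8, 8)))$delta_t_frames[, , 1]
    want_full <- box_mean_oracle(arr[, , 1], matrix(TRUE, 8, 8), 3)
    expect_equal(got_full, want_full, tolerance = 1e-12)
  }
})

test_that("smoothed values stay within the local input range", {
  withr::with_seed(11, {
    arr <- array(stats::rnorm(12 * 12 * 3), c(12, 12, 3))
  })
  ts <- temperature_series(arr, 0:2)
  out <- smooth_temperature(ts, full_mask(c(12, 12)))
  expect_lte(max(out$delta_t_frames), max(arr) + 1e-12)
  expect_gte(min(out$delta_t_frames), min(arr) - 1e-12)
})

test_that("even smoothing widths are rejected", {
  ts <- temperature_series(array(0, c(4, 4, 1)), 0)
  expect_error(smooth_temperature(ts, full_mask(c(4, 4)), width = 4), "odd")
})
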