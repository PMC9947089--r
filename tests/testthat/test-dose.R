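test_that("pixel area follows FOV / matrix geometry", {
  expect_equal(round(pixel_area(acquisition_params()), 2), 1.82)
  expect_equal(pixel_area(acquisition_params(fov_mm = c(100, 100),
                                             matrix_size = c(100, 100))), 1)
  expect_equal(pixel_area(acquisition_params(fov_mm = c(10, 20),
                                             matrix_size = c(8, 8))),
               (10 / 8) * (20 / 8))
})

test_that("holding the breakpoint temperature accrues clock time", {
  # constant 43 C for 60 one-minute frames: dose = 60 equivalent minutes
  n <- 60
  ts <- temperature_series(array(6, c(2, 2, n)),
                           seq(0, by = 60, length.out = n))
  dm <- cem43(ts, full_mask(c(2, 2)), dose_params(), pixel_area_mm2 = 1,
              dt_s = 60)
  expect_equal(dm$cem43_min, matrix(60, 2, 2), tolerance = 1e-12)
})

test_that("one degree above the breakpoint doubles the equivalent time", {
  n <- 60
  ts <- temperature_series(array(7, c(1, 1, n)),
                           seq(0, by = 60, length.out = n))
  dm <- cem43(ts, full_mask(c(1, 1)), dose_params(), pixel_area_mm2 = 1,
              dt_s = 60)
  expect_equal(dm$cem43_min[1, 1], 120, tolerance = 1e-12)
})

test_that("no dose accrues below the accrual floor", {
  ts <- temperature_series(array(1, c(1, 1, 10)), 0:9)   # 38 C < 39 C floor
  dm <- cem43(ts, full_mask(c(1, 1)), dose_params(), dt_s = 60)
  expect_equal(dm$cem43_min[1, 1], 0)
})

test_that("vectorized dose equals the scalar per-pixel oracle", {
  params <- dose_params()
  for (seed in 1:3) {
    withr::with_seed(seed, {
      arr <- array(stats::runif(6 * 5 * 200, -2, 15), c(6, 5, 200))
      keep <- matrix(stats::runif(30) > 0.2, 6, 5)
    })
    ts <- temperature_series(arr, 0.62 * (0:199), baseline_temp_C = 37)
    dm <- cem43(ts, pixel_mask(keep), params, dt_s = 0.62)
    want <- cem43_oracle(arr, keep, 37, 0.62, params)
    expect_equal(dm$cem43_min, want, tolerance = 1e-12)
  }
})

test_that("dose is additive over a frame split", {
  withr::with_seed(4, {
    arr <- array(stats::runif(4 * 4 * 50, 0, 12), c(4, 4, 50))
  })
  mk <- full_mask(c(4, 4))
  t_all <- 0.62 * (0:49)
  full <- cem43(temperature_series(arr, t_all), mk, dt_s = 0.62)
  head_ <- cem43(temperature_series(arr[, , 1:20, drop = FALSE],
                                    t_all[1:20]), mk, dt_s = 0.62)
  tail_ <- cem43(temperature_series(arr[, , 21:50, drop = FALSE],
                                    t_all[21:50]), mk, dt_s = 0.62)
  expect_equal(full$cem43_min, head_$cem43_min + tail_$cem43_min,
               tolerance = 1e-12)
})

test_that("a pointwise-hotter series never gets a lower dose", {
  withr::with_seed(5, {
    arr <- array(stats::runif(5 * 5 * 40, 0, 10), c(5, 5, 40))
    bump <- array(stats::runif(5 * 5 * 40, 0, 3), c(5, 5, 40))
  })
  mk <- full_mask(c(5, 5))
  d1 <- cem43(temperature_series(arr, 0:39), mk, dt_s = 0.62)
  d2 <- cem43(temperature_series(arr + bump, 0:39), mk, dt_s = 0.62)
  expect_true(all(d2$cem43_min >= d1$cem43_min - 1e-12))
})

test_that("non-finite temperatures at kept pixels are reported with location", {
  arr <- array(0, c(3, 3, 4)); arr[2, 3, 2] <- NA
  ts <- temperature_series(arr, 0:3)
  expect_error(cem43(ts, full_mask(c(3, 3)), dt_s = 1), "\\(2, 3\\), frame 2")
  # masked-out pixels may be non-finite
  keep <- matrix(TRUE, 3, 3); keep[2, 3] <- FALSE
  expect_silent(cem43(ts, pixel_mask(keep), dt_s = 1))
})

test_that("critical area counts strictly-over-threshold kept pixels", {
  dose <- matrix(0, 6, 6)
  dose[2, 2] <- 120      # not strictly over
  dose[cbind(c(3, 3, 4, 4, 5), c(2, 3, 2, 3, 5))] <- 150
  dm <- structure(list(cem43_min = dose, pixel_area_mm2 = 1.82),
                  class = "dose_map")
  ts <- temperature_series(array(0, c(6, 6, 2)), 0:1)
  res <- critical_area(dm, ts, full_mask(c(6, 6)))
  expect_equal(res$n_pixels, 5L)
  expect_equal(res$area_mm2, 5 * 1.82)
})

test_that("critical area equals an exhaustive scan on random dose maps", {
  for (seed in 1:4) {
    withr::with_seed(seed, {
      dose <- matrix(stats::runif(100, 0, 300), 10, 10)
      keep <- matrix(stats::runif(100) > 0.3, 10, 10)
    })
    dm <- structure(list(cem43_min = dose, pixel_area_mm2 = 2),
                    class = "dose_map")
    ts <- temperature_series(array(0, c(10, 10, 2)), 0:1)
    res <- critical_area(dm, ts, pixel_mask(keep))
    brute <- 0L
    for (i in 1:10) for (j in 1:10)
      if (keep[i, j] && dose[i, j] > 120) brute <- brute + 1L
    expect_equal(res$n_pixels, brute)
    expect_equal(res$area_mm2, brute * 2)
  }
})

test_that("the hottest pixel is the kept argmax with row-major tie-breaking", {
  arr <- array(0, c(4, 4, 3))
  arr[2, 3, 2] <- 5
  arr[3, 1, 3] <- 5      # tie: (2,3) precedes (3,1) in row-major order
  ts <- temperature_series(arr, 0:2)
  dm <- cem43(ts, full_mask(c(4, 4)), dt_s = 1)
  res <- critical_area(dm, ts, full_mask(c(4, 4)))
  expect_equal(res$hottest_pixel, c(2, 3))
  expect_equal(res$max_delta_t_C, 5)
  expect_equal(res$hottest_curve, arr[2, 3, ])
  # excluding the winner hands the title to the row-major successor
  keep <- matrix(TRUE, 4, 4); keep[2, 3] <- FALSE
  res2 <- critical_area(dm, ts, pixel_mask(keep))
  expect_equal(res2$hottest_pixel, c(3, 1))
})

test_that("an empty mask yields a flagged zero-area result", {
  ts <- temperature_series(array(0, c(3, 3, 2)), 0:1)
  dm <- cem43(ts, pixel_mask(matrix(FALSE, 3, 3)), dt_s = 1)
  res <- critical_area(dm, ts, pixel_mask(matrix(FALSE, 3, 3)))
  expect_true(res$empty_mask)
  expect_equal(res$area_mm2, 0)
  expect_true(all(is.na(res$hottest_pixel)))
})

test_that("dose parameter invariants are enforced", {
  expect_error(dose_params(r_above = 1.2), "R values")
  expect_error(dose_params(t_floor_C = 45), "t_floor")
  expect_error(dose_params(threshold_min = 0), "threshold")
})
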