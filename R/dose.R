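#' CEM43 dose model parameters
#'
#' Constants of the cumulative-equivalent-minutes thermal dose model. One
#' minute at temperature `T` is worth `R^(t_break_C - T)` equivalent minutes
#' at the 43 degree C reference, with `R = r_above` (0.5) at or above the
#' breakpoint and `r_below` (0.25) beneath it; no dose accrues below
#' `t_floor_C` (39). Doses above `threshold_min` (120 equivalent minutes)
#' are considered to damage most tissues, including renal parenchyma.
#'
#' @param t_break_C Breakpoint temperature, degrees C.
#' @param r_above R for `T >= t_break_C` (0 < R < 1).
#' @param r_below R for `t_floor_C <= T < t_break_C` (0 < R < 1).
#' @param t_floor_C Temperature below which no dose accrues, degrees C.
#' @param threshold_min Critical dose threshold, equivalent minutes.
#' @return An object of class `dose_params`.
#' @export
dose_params <- function(t_break_C = 43, r_above = 0.5, r_below = 0.25,
                        t_floor_C = 39, threshold_min = 120) {
  if (r_above <= 0 || r_above >= 1 || r_below <= 0 || r_below >= 1)
    stop("R values must lie in (0, 1)", call. = FALSE)
  if (t_floor_C > t_break_C)
    stop("t_floor_C must not exceed t_break_C", call. = FALSE)
  if (threshold_min <= 0) stop("threshold_min must be > 0", call. = FALSE)
  structure(list(t_break_C = t_break_C, r_above = r_above,
                 r_below = r_below, t_floor_C = t_floor_C,
                 threshold_min = threshold_min),
            class = "dose_params")
}

#' In-plane area per pixel from acquisition geometry
#'
#' `(fov_rows / matrix_rows) * (fov_cols / matrix_cols)`. The default
#' acquisition (FOV 235 x 259 mm^2, matrix 174 x 192) gives 1.82 mm^2.
#'
#' @param acq An [acquisition_params()].
#' @return Pixel area in mm^2.
#' @export
pixel_area <- function(acq) {
  stopifnot(inherits(acq, "acquisition_params"))
  if (any(acq$matrix_size == 0))
    stop("matrix dimensions must be non-zero", call. = FALSE)
  prod(acq$fov_mm / acq$matrix_size)
}

#' Per-pixel CEM43 thermal dose map
#'
#' Accumulates, for every kept pixel, the cumulative equivalent minutes at
#' 43 degrees C over the temperature series:
#' \deqn{CEM_{43} = \sum_k \Delta t_{min} \; R(T_k)^{43 - T_k}}
#' with absolute temperature `T_k = baseline_temp_C + dT_k`, `R` as in
#' [dose_params()], zero contribution below the accrual floor, and
#' `dt_min` the frame interval in minutes. Excluded pixels carry dose 0.
#'
#' @param temps A [temperature_series()].
#' @param mask A [pixel_mask()].
#' @param params A [dose_params()].
#' @param pixel_area_mm2 Area per pixel, mm^2 (see [pixel_area()]).
#' @param dt_s Frame interval, seconds; defaults to the median spacing of
#'   `temps$times_s`.
#' @return An object of class `dose_map` with fields `cem43_min` (matrix)
#'   and `pixel_area_mm2`.
#' @examples
#' # one pixel held 1 K above the breakpoint for an hour doubles the clock:
#' ts <- temperature_series(array(7, c(1, 1, 60)), seq(0, by = 60, length = 60))
#' mk <- pixel_mask(matrix(TRUE, 1, 1))
#' cem43(ts, mk, dose_params(), pixel_area_mm2 = 1, dt_s = 60)$cem43_min
#' @export
cem43 <- function(temps, mask, params = dose_params(), pixel_area_mm2 = 1.82,
                  dt_s = NULL) {
  stopifnot(inherits(temps, "temperature_series"),
            inherits(mask, "pixel_mask"),
            inherits(params, "dose_params"))
  dt_arr <- temps$delta_t_frames
  if (!identical(dim(dt_arr)[1:2], dim(mask$keep)))
    stop("mask shape does not match the temperature frames", call. = FALSE)
  if (is.null(dt_s)) {
    if (length(temps$times_s) < 2)
      stop("cannot infer the frame interval from a single frame",
           call. = FALSE)
    dt_s <- stats::median(diff(temps$times_s))
  }
  dt_min <- dt_s / 60
  keep <- mask$keep
  n <- dim(dt_arr)[3]
  dose <- matrix(0, nrow(keep), ncol(keep))
  for (k in seq_len(n)) {
    temp_abs <- temps$baseline_temp_C + dt_arr[, , k]
    if (any(!is.finite(temp_abs[keep]))) {
      idx <- which(keep & !is.finite(temp_abs), arr.ind = TRUE)[1, ]
      stop(sprintf("non-finite temperature at pixel (%d, %d), frame %d",
                   idx[1], idx[2], k), call. = FALSE)
    }
    r <- ifelse(temp_abs >= params$t_break_C, params$r_above, params$r_below)
    contrib <- dt_min * r^(params$t_break_C - temp_abs)
    contrib[temp_abs < params$t_floor_C] <- 0
    dose <- dose + contrib
  }
  dose[!keep] <- 0
  structure(list(cem43_min = dose, pixel_area_mm2 = pixel_area_mm2),
            class = "dose_map")
}

#' @export
print.dose_map <- function(x, ...) {
  cat(sprintf("CEM43 dose map: %d x %d, max %.1f equivalent min, %.2f mm^2/px\n",
              nrow(x$cem43_min), ncol(x$cem43_min), max(x$cem43_min),
              x$pixel_area_mm2))
  invisible(x)
}

#' Critical thermal-dose area and hottest pixel
#'
#' Sums the area of all kept pixels whose CEM43 strictly exceeds the
#' critical threshold, and locates the pixel with the highest temperature
#' difference among the kept pixels (argmax of the per-pixel maximum over
#' time, ties broken in row-major order), returning its temperature-time
#' course.
#'
#' @param dose A `dose_map` from [cem43()].
#' @param temps The [temperature_series()] the dose was computed from.
#' @param mask The [pixel_mask()] used.
#' @param params A [dose_params()] (supplies the threshold).
#' @return An object of class `critical_area_result` with fields
#'   `area_mm2`, `n_pixels`, `hottest_pixel` (row, col; `NA` when the mask
#'   is empty), `hottest_curve`, `max_delta_t_C` and `empty_mask`.
#' @export
critical_area <- function(dose, temps, mask, params = dose_params()) {
  stopifnot(inherits(dose, "dose_map"),
            inherits(temps, "temperature_series"),
            inherits(mask, "pixel_mask"))
  keep <- mask$keep
  if (!identical(dim(dose$cem43_min), dim(keep)))
    stop("dose and mask shapes differ", call. = FALSE)
  over <- keep & dose$cem43_min > params$threshold_min
  n_pixels <- sum(over)
  area <- n_pixels * dose$pixel_area_mm2
  if (mask$n_kept == 0) {
    return(structure(list(area_mm2 = 0, n_pixels = 0L,
                          hottest_pixel = c(NA_integer_, NA_integer_),
                          hottest_curve = rep(NA_real_,
                                              length(temps$times_s)),
                          times_s = temps$times_s,
                          max_delta_t_C = NA_real_, empty_mask = TRUE),
                     class = "critical_area_result"))
  }
  peak <- apply(temps$delta_t_frames, c(1, 2), max)
  peak[!keep] <- -Inf
  # which.max scans column-major; transpose for row-major tie-breaking
  tp <- t(peak)
  flat <- which.max(tp)
  col <- (flat - 1L) %% nrow(tp) + 1L
  row <- (flat - 1L) %/% nrow(tp) + 1L
  structure(list(area_mm2 = area, n_pixels = as.integer(n_pixels),
                 hottest_pixel = c(row, col),
                 hottest_curve = temps$delta_t_frames[row, col, ],
                 times_s = temps$times_s,
                 max_delta_t_C = peak[row, col], empty_mask = FALSE),
            class = "critical_area_result")
}

#' @export
print.critical_area_result <- function(x, ...) {
  if (isTRUE(x$empty_mask)) {
    cat("Critical area: empty mask (no pixels analysed)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "Critical area: %.1f mm^2 (%d px); hottest pixel (%d, %d), max dT %.1f C\n",
    x$area_mm2, x$n_pixels, x$hottest_pixel[1], x$hottest_pixel[2],
    x$max_delta_t_C))
  invisible(x)
}
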