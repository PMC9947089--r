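#' Gyromagnetic ratio of the proton, Hz per Tesla
#'
#' Used by the PRF phase model in [encode_mr_series()] and
#' [reconstruct_delta_t()].
#' @export
GAMMA_HZ_PER_T <- 42.577e6

#' Default PRF thermal coefficient, ppm per degree Celsius
#'
#' Literature-standard temperature dependence of the water proton resonance
#' frequency. Negative: heating lowers the resonance frequency, so with a
#' positive echo time the phase decreases and the reconstruction maps a
#' negative phase change to a positive temperature rise.
#' @export
PRF_COEFF_DEFAULT <- -0.01

#' Pulsed-laser application protocol
#'
#' Describes an intermittent Ho:YAG application pattern: the laser is on for
#' `t_on_s` seconds, then off for `t_off_s` seconds, repeated
#' `n_applications` times. The study protocols are `t_on/t_off` of
#' 5/5, 5/10, 10/5, 10/10 and 20/0 seconds at 14 W or 30 W, normally applied
#' three times in a row.
#'
#' @param power_watts Laser power in W (non-negative).
#' @param t_on_s Application (laser-on) time per cycle in seconds (> 0).
#' @param t_off_s Intermittent delay between applications in seconds (>= 0).
#' @param n_applications Number of on/off cycles (>= 1).
#' @return An object of class `laser_protocol`.
#' @examples
#' laser_protocol(30, t_on_s = 10, t_off_s = 5)
#' @export
laser_protocol <- function(power_watts, t_on_s, t_off_s, n_applications = 3) {
  stopifnot(is.numeric(power_watts), length(power_watts) == 1,
            is.numeric(t_on_s), length(t_on_s) == 1,
            is.numeric(t_off_s), length(t_off_s) == 1)
  if (power_watts < 0) stop("power_watts must be >= 0", call. = FALSE)
  if (t_on_s <= 0) stop("t_on_s must be > 0", call. = FALSE)
  if (t_off_s < 0) stop("t_off_s must be >= 0", call. = FALSE)
  n_applications <- as.integer(n_applications)
  if (is.na(n_applications) || n_applications < 1)
    stop("n_applications must be >= 1", call. = FALSE)
  structure(
    list(power_watts = power_watts, t_on_s = t_on_s, t_off_s = t_off_s,
         n_applications = n_applications),
    class = "laser_protocol")
}

#' Total on + off duration of a protocol, seconds
#' @param protocol A [laser_protocol()].
#' @return Length-one numeric, seconds.
#' @export
protocol_duration <- function(protocol) {
  stopifnot(inherits(protocol, "laser_protocol"))
  protocol$n_applications * (protocol$t_on_s + protocol$t_off_s)
}

#' Laser on/off state at given times
#'
#' The first application starts at `start_s`; each cycle is `t_on_s` on then
#' `t_off_s` off. The state is on over the half-open interval
#' `[cycle start, cycle start + t_on_s)`.
#'
#' @param protocol A [laser_protocol()].
#' @param times_s Numeric vector of times, seconds.
#' @param start_s Time at which the first application begins (default 0).
#' @return Logical vector, `TRUE` where the laser is firing.
#' @export
laser_on_at <- function(protocol, times_s, start_s = 0) {
  stopifnot(inherits(protocol, "laser_protocol"))
  t <- times_s - start_s
  cycle <- protocol$t_on_s + protocol$t_off_s
  total <- protocol$n_applications * cycle
  in_train <- t >= 0 & t < total
  # 20/0 s continuous protocols have a zero off phase: on for the whole train
  if (protocol$t_off_s == 0) return(in_train)
  in_train & (t %% cycle) < protocol$t_on_s
}

#' @export
print.laser_protocol <- function(x, ...) {
  cat(sprintf("Laser protocol: %g W, t_on/t_off = %g/%g s x %d applications\n",
              x$power_watts, x$t_on_s, x$t_off_s, x$n_applications))
  invisible(x)
}

#' MR acquisition parameters
#'
#' Geometry and timing of the dynamic gradient-echo (segmented EPI)
#' acquisition used for PRF thermometry. Defaults follow a clinical 1.5 T
#' protocol: TR 31 ms, TE 15 ms, flip 13 degrees, slice 4 mm, FOV
#' 235 x 259 mm^2, matrix 174 x 192 (1.82 mm^2 per pixel) and 620 ms per
#' dynamic frame.
#'
#' @param te_s Echo time, seconds (> 0).
#' @param tr_s Repetition time, seconds.
#' @param flip_deg Flip angle, degrees.
#' @param slice_mm Slice thickness, mm.
#' @param fov_mm Length-two numeric, field of view extents (row, col), mm.
#' @param matrix_size Length-two integer, acquisition matrix (rows, cols).
#' @param frame_interval_s Acquisition time per dynamic image (TA), seconds.
#' @param b0_tesla Static field strength, Tesla.
#' @return An object of class `acquisition_params`.
#' @examples
#' acq <- acquisition_params()
#' pixel_area(acq)   # 1.82 mm^2 to two decimals
#' @export
acquisition_params <- function(te_s = 0.015, tr_s = 0.031, flip_deg = 13,
                               slice_mm = 4, fov_mm = c(235, 259),
                               matrix_size = c(174L, 192L),
                               frame_interval_s = 0.62, b0_tesla = 1.5) {
  if (te_s <= 0) stop("te_s must be > 0", call. = FALSE)
  if (frame_interval_s <= 0) stop("frame_interval_s must be > 0", call. = FALSE)
  matrix_size <- as.integer(matrix_size)
  stopifnot(length(fov_mm) == 2, length(matrix_size) == 2)
  if (any(matrix_size < 8L))
    stop("matrix dimensions must be >= 8", call. = FALSE)
  if (any(fov_mm <= 0)) stop("fov_mm must be positive", call. = FALSE)
  if (b0_tesla <= 0) stop("b0_tesla must be > 0", call. = FALSE)
  structure(
    list(te_s = te_s, tr_s = tr_s, flip_deg = flip_deg, slice_mm = slice_mm,
         fov_mm = as.numeric(fov_mm), matrix_size = matrix_size,
         frame_interval_s = frame_interval_s, b0_tesla = b0_tesla),
    class = "acquisition_params")
}

#' In-plane pixel edge lengths of an acquisition, mm
#' @param acq An [acquisition_params()].
#' @return Length-two numeric `(row pitch, column pitch)` in mm.
#' @export
pixel_pitch <- function(acq) {
  stopifnot(inherits(acq, "acquisition_params"))
  acq$fov_mm / acq$matrix_size
}

#' @export
print.acquisition_params <- function(x, ...) {
  cat(sprintf(paste0("MR acquisition: %.1f T, TE %.0f ms, TA %.0f ms, ",
                     "FOV %g x %g mm^2, matrix %d x %d\n"),
              x$b0_tesla, x$te_s * 1e3, x$frame_interval_s * 1e3,
              x$fov_mm[1], x$fov_mm[2], x$matrix_size[1], x$matrix_size[2]))
  invisible(x)
}
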