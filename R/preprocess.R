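#' Pixel inclusion mask
#'
#' A boolean raster of pixels retained for analysis, with a provenance
#' record of how many pixels each exclusion rule removed.
#'
#' @param keep Logical matrix, `TRUE` for retained pixels.
#' @param provenance Named list describing the applied rules and the counts
#'   they removed.
#' @return An object of class `pixel_mask` with fields `keep`, `n_kept`,
#'   `provenance`.
#' @export
pixel_mask <- function(keep, provenance = list()) {
  stopifnot(is.logical(keep), is.matrix(keep))
  structure(list(keep = keep, n_kept = sum(keep), provenance = provenance),
            class = "pixel_mask")
}

#' @export
print.pixel_mask <- function(x, ...) {
  cat(sprintf("Pixel mask: %d of %d pixels kept\n", x$n_kept,
              length(x$keep)))
  for (nm in names(x$provenance))
    cat(sprintf("  %s: removed %d\n", nm, x$provenance[[nm]]$removed))
  invisible(x)
}

#' Region of interest
#'
#' Either a polygon (matrix of `(row, col)` vertices in pixel coordinates,
#' where pixel `(r, c)` has its centre at `(r, c)`) or a boolean raster of
#' the frame shape.
#'
#' @param x An `n x 2` numeric matrix of polygon vertices (>= 3 rows), or a
#'   logical matrix raster.
#' @return An object of class `roi_spec` of kind `"polygon"` or `"raster"`.
#' @export
roi_spec <- function(x) {
  if (is.logical(x) && is.matrix(x)) {
    return(structure(list(kind = "raster", raster = x), class = "roi_spec"))
  }
  if (is.numeric(x) && is.matrix(x) && ncol(x) == 2) {
    if (nrow(x) < 3)
      stop("polygon ROI needs at least 3 vertices", call. = FALSE)
    return(structure(list(kind = "polygon", vertices = x), class = "roi_spec"))
  }
  stop("roi must be an n x 2 vertex matrix or a logical raster", call. = FALSE)
}

#' Rectangular border ROI (air region of a synthetic frame)
#'
#' @param shape Length-two integer raster shape.
#' @param width Border width in pixels.
#' @return A raster [roi_spec()] marking the border pixels.
#' @export
border_roi <- function(shape, width = 4L) {
  shape <- as.integer(shape); width <- as.integer(width)
  m <- matrix(FALSE, shape[1], shape[2])
  m[c(seq_len(width), shape[1] - seq_len(width) + 1L), ] <- TRUE
  m[, c(seq_len(width), shape[2] - seq_len(width) + 1L)] <- TRUE
  roi_spec(m)
}

#' Rasterize an ROI onto a frame grid
#'
#' Polygon ROIs include every pixel whose centre lies inside the polygon
#' under the even-odd (ray crossing) rule; raster ROIs are returned as-is.
#' Pixel `(r, c)` (1-based) has its centre at coordinates `(r, c)`.
#'
#' @param roi A [roi_spec()].
#' @param shape Length-two integer frame shape.
#' @return Logical matrix of `shape`.
#' @export
rasterize_roi <- function(roi, shape) {
  stopifnot(inherits(roi, "roi_spec"))
  shape <- as.integer(shape)
  if (roi$kind == "raster") {
    if (!all(dim(roi$raster) == shape))
      stop("raster ROI shape does not match the frame", call. = FALSE)
    return(roi$raster)
  }
  v <- roi$vertices
  # degenerate (zero-area) polygons select nothing and are a usage error
  area2 <- sum(v[, 1] * v[c(2:nrow(v), 1), 2] -
               v[c(2:nrow(v), 1), 1] * v[, 2])
  if (abs(area2) < .Machine$double.eps * 100)
    stop("degenerate polygon ROI (zero area)", call. = FALSE)
  py <- matrix(seq_len(shape[1]), shape[1], shape[2])          # row coord
  px <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  inside <- matrix(FALSE, shape[1], shape[2])
  nv <- nrow(v)
  j <- nv
  for (i in seq_len(nv)) {
    y1 <- v[i, 1]; x1 <- v[i, 2]
    y2 <- v[j, 1]; x2 <- v[j, 2]
    crosses <- (y1 > py) != (y2 > py)
    if (any(crosses)) {
      xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      flip <- crosses & (px < xint)
      inside[flip] <- !inside[flip]
    }
    j <- i
  }
  inside
}

#' Magnitude-based noise mask
#'
#' Pixels whose MR signal magnitude is too close to the noise floor carry
#' unusable phase and are excluded: a pixel is kept when its mean baseline
#' magnitude is at least `factor` times the mean air signal, i.e. pixels
#' with `S < factor * S_air` are removed (default factor 3.7). `S_air` is
#' the mean magnitude over the air ROI across the baseline frames.
#'
#' @param series A [dynamic_series()], or a 3D array of baseline magnitude
#'   frames.
#' @param air_roi A [roi_spec()] marking air (outside the object).
#' @param factor Threshold multiplier (> 0), default 3.7.
#' @return A [pixel_mask()].
#' @export
noise_mask <- function(series, air_roi, factor = 3.7) {
  if (inherits(series, "dynamic_series")) {
    mag <- series$magnitude_frames[, , seq_len(series$baseline_frame_count),
                                   drop = FALSE]
  } else {
    stopifnot(is.array(series), length(dim(series)) == 3)
    mag <- series
  }
  if (factor <= 0) stop("factor must be > 0", call. = FALSE)
  shape <- dim(mag)[1:2]
  air <- rasterize_roi(air_roi, shape)
  if (!any(air)) stop("air ROI is empty", call. = FALSE)
  n <- dim(mag)[3]
  mean_mag <- matrix(0, shape[1], shape[2])
  for (k in seq_len(n)) mean_mag <- mean_mag + mag[, , k]
  mean_mag <- mean_mag / n
  s_air <- mean(mean_mag[air])
  keep <- mean_mag >= factor * s_air
  pixel_mask(keep, provenance = list(
    noise = list(rule = sprintf("S < %g * S_air", factor), s_air = s_air,
                 removed = sum(!keep))))
}

#' Restrict a mask to a region of interest
#'
#' Intersects the kept pixels with the (rasterized) ROI, e.g. a manually
#' drawn kidney outline that excludes the ureter and flow regions outside
#' the organ. Idempotent.
#'
#' @param mask A [pixel_mask()].
#' @param roi A [roi_spec()].
#' @return A new [pixel_mask()] with updated provenance.
#' @export
apply_roi <- function(mask, roi) {
  stopifnot(inherits(mask, "pixel_mask"))
  r <- rasterize_roi(roi, dim(mask$keep))
  keep <- mask$keep & r
  prov <- mask$provenance
  prov$roi <- list(rule = "kidney ROI", removed = mask$n_kept - sum(keep))
  pixel_mask(keep, provenance = prov)
}

# mask-aware box mean of a single frame: each kept pixel becomes the mean
# of kept pixels in its w x w in-frame neighbourhood
box_mean_masked <- function(frame, keep, width) {
  half <- (width - 1L) %/% 2L
  nr <- nrow(frame); nc <- ncol(frame)
  vals <- frame
  vals[!keep] <- 0
  acc <- matrix(0, nr, nc)
  cnt <- matrix(0, nr, nc)
  for (dr in -half:half) {
    r_src <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
    valid_r <- seq_len(nr) + dr >= 1L & seq_len(nr) + dr <= nr
    for (dc in -half:half) {
      c_src <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
      valid_c <- seq_len(nc) + dc >= 1L & seq_len(nc) + dc <= nc
      w <- outer(valid_r, valid_c, "&") * keep[r_src, c_src]
      acc <- acc + vals[r_src, c_src] * w
      cnt <- cnt + w
    }
  }
  out <- frame
  idx <- keep & cnt > 0
  out[idx] <- acc[idx] / cnt[idx]
  out
}

#' Mask-aware spatial smoothing of temperature maps
#'
#' Applies an averaging (box) filter of odd width (default 3 x 3) to each
#' temperature frame to reduce phase noise. The filter is mask-aware: each
#' kept pixel becomes the mean of the *kept* pixels in its neighbourhood
#' (renormalized, not zero-padded, so values near the lesion rim and the
#' frame border are not biased toward zero); excluded pixels contribute
#' nothing and keep their original values.
#'
#' @param temps A [temperature_series()].
#' @param mask A [pixel_mask()]; pass a full mask to smooth everywhere.
#' @param width Odd kernel width, default 3.
#' @return A smoothed [temperature_series()].
#' @export
smooth_temperature <- function(temps, mask, width = 3L) {
  stopifnot(inherits(temps, "temperature_series"),
            inherits(mask, "pixel_mask"))
  width <- as.integer(width)
  if (width %% 2L == 0L) stop("kernel width must be odd", call. = FALSE)
  out <- temps$delta_t_frames
  for (k in seq_len(dim(out)[3]))
    out[, , k] <- box_mean_masked(out[, , k], mask$keep, width)
  temperature_series(out, temps$times_s, temps$baseline_temp_C)
}
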