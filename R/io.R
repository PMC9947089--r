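#' Write a numeric matrix as a tab-separated text file
#'
#' Full double precision, one raster row per line. The plain-text matrix
#' format is the package's portable export for temperature and dose maps.
#'
#' @param mat Numeric matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_matrix_txt <- function(mat, path) {
  utils::write.table(format(mat, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a tab-separated text matrix written by [write_matrix_txt()]
#' @param path File path.
#' @return Numeric matrix.
#' @export
read_matrix_txt <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                              colClasses = "numeric"))
}

#' Write a dynamic series as a portable array container
#'
#' One directory holding per-frame magnitude and phase rasters as
#' tab-separated text plus a `series.json` sidecar with the timestamps,
#' acquisition metadata and baseline frame count.
#'
#' @param series A [dynamic_series()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_series <- function(series, dir) {
  stopifnot(inherits(series, "dynamic_series"))
  dir.create(file.path(dir, "magnitude"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "phase"), recursive = TRUE, showWarnings = FALSE)
  n <- dim(series$magnitude_frames)[3]
  for (k in seq_len(n)) {
    write_matrix_txt(series$magnitude_frames[, , k],
                     file.path(dir, "magnitude", sprintf("frame_%04d.txt", k)))
    write_matrix_txt(series$phase_frames[, , k],
                     file.path(dir, "phase", sprintf("frame_%04d.txt", k)))
  }
  meta <- list(times_s = series$times_s,
               baseline_frame_count = series$baseline_frame_count,
               n_frames = n, shape = dim(series$magnitude_frames)[1:2],
               acq = unclass(series$acq))
  jsonlite::write_json(meta, file.path(dir, "series.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a dynamic series written by [write_series()]
#' @param dir Container directory.
#' @return A [dynamic_series()].
#' @export
read_series <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "series.json"),
                              simplifyVector = TRUE)
  n <- meta$n_frames
  shape <- as.integer(meta$shape)
  mag <- array(NA_real_, c(shape, n))
  ph <- array(NA_real_, c(shape, n))
  for (k in seq_len(n)) {
    mag[, , k] <- read_matrix_txt(
      file.path(dir, "magnitude", sprintf("frame_%04d.txt", k)))
    ph[, , k] <- read_matrix_txt(
      file.path(dir, "phase", sprintf("frame_%04d.txt", k)))
  }
  acq <- do.call(acquisition_params, meta$acq)
  dynamic_series(mag, ph, meta$times_s, acq, meta$baseline_frame_count)
}

#' Write a dose map (text matrix + JSON sidecar)
#' @param dose A `dose_map` from [cem43()].
#' @param path Output path for the matrix; a `.json` sidecar is written
#'   alongside.
#' @return `path`, invisibly.
#' @export
write_dose_map <- function(dose, path) {
  stopifnot(inherits(dose, "dose_map"))
  write_matrix_txt(dose$cem43_min, path)
  jsonlite::write_json(
    list(pixel_area_mm2 = dose$pixel_area_mm2, units = "equivalent min at 43 C"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
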