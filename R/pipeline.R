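#' Configure a single thermometry experiment
#'
#' Bundles everything one analysis run needs. The source is either a
#' simulation (a [laser_protocol()] plus a [thermal_scene()] plus a seed) or
#' a previously stored dynamic series (a portable container directory, see
#' [write_series()]); exactly one of the two must be given.
#'
#' @param protocol A [laser_protocol()] (simulation source).
#' @param scene A [thermal_scene()] (simulation source).
#' @param series_dir Directory of a stored series (file source).
#' @param acq An [acquisition_params()]; when `NULL` and simulating, one is
#'   derived from the scene grid (same pixel pitch, default timing).
#' @param air_roi,kidney_roi [roi_spec()]s. When simulating, defaults are
#'   the encoder's air border and the cavity+tissue region of the scene.
#' @param dose A [dose_params()].
#' @param prf_coeff_ppm_per_C PRF coefficient, ppm per degree C.
#' @param noise_sd Complex noise standard deviation for the encoder.
#' @param air_margin_px Air border width for the encoder, pixels.
#' @param duration_s Simulated duration; default covers the protocol train
#'   plus the pre-heating delay plus 30 s of cool-down.
#' @param laser_start_s Pre-heating delay, seconds.
#' @param smooth Logical, apply the 3 x 3 averaging filter (default TRUE).
#' @param smooth_width Odd filter width.
#' @param seed Integer seed for the encoder noise.
#' @param run_id Character label for the summary row.
#' @param fiber_site Character label (`"calyx"`, `"pelvis"`, ...).
#' @param baseline_temp_C Absolute baseline temperature, degrees C.
#' @param output_dir Directory for artifacts (dose map, summary CSV,
#'   provenance JSON); `NULL` writes nothing.
#' @param qc_excluded Logical; `TRUE` marks the run as excluded for
#'   image artifacts (e.g. air suction) — the run is skipped.
#' @param qc_reason Character reason recorded with an excluded run.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(protocol = NULL, scene = NULL,
                              series_dir = NULL, acq = NULL,
                              air_roi = NULL, kidney_roi = NULL,
                              dose = dose_params(),
                              prf_coeff_ppm_per_C = PRF_COEFF_DEFAULT,
                              noise_sd = 2, air_margin_px = 4L,
                              duration_s = NULL, laser_start_s = 5,
                              smooth = TRUE, smooth_width = 3L,
                              seed = 1L, run_id = "run",
                              fiber_site = "calyx", baseline_temp_C = 37,
                              output_dir = NULL, qc_excluded = FALSE,
                              qc_reason = "") {
  simulated <- !is.null(protocol) || !is.null(scene)
  from_file <- !is.null(series_dir)
  if (simulated == from_file)
    stop("exactly one source: protocol+scene, or series_dir", call. = FALSE)
  if (simulated) {
    stopifnot(inherits(protocol, "laser_protocol"),
              inherits(scene, "thermal_scene"))
    if (is.null(acq))
      acq <- acquisition_params(
        fov_mm = scene$grid_shape * scene$pixel_mm,
        matrix_size = scene$grid_shape)
    if (is.null(duration_s))
      duration_s <- laser_start_s + protocol_duration(protocol) + 30
    baseline_temp_C <- scene$baseline_temp_C
  } else if (is.null(air_roi) || is.null(kidney_roi)) {
    stop("file sources need explicit air_roi and kidney_roi", call. = FALSE)
  }
  structure(
    list(protocol = protocol, scene = scene, series_dir = series_dir,
         acq = acq, air_roi = air_roi, kidney_roi = kidney_roi,
         dose = dose, prf_coeff_ppm_per_C = prf_coeff_ppm_per_C,
         noise_sd = noise_sd, air_margin_px = as.integer(air_margin_px),
         duration_s = duration_s, laser_start_s = laser_start_s,
         smooth = smooth, smooth_width = as.integer(smooth_width),
         seed = as.integer(seed), run_id = run_id, fiber_site = fiber_site,
         baseline_temp_C = baseline_temp_C, output_dir = output_dir,
         qc_excluded = isTRUE(qc_excluded), qc_reason = qc_reason),
    class = "experiment_config")
}

summary_columns <- c("run_id", "power_W", "t_on_s", "t_off_s",
                     "irrigation_ml_min", "fiber_site", "area_mm2",
                     "n_pixels", "max_delta_t_C", "hottest_row",
                     "hottest_col", "qc_flag")

summary_row <- function(config, result) {
  pr <- config$protocol
  data.frame(
    run_id = config$run_id,
    power_W = if (is.null(pr)) NA_real_ else pr$power_watts,
    t_on_s = if (is.null(pr)) NA_real_ else pr$t_on_s,
    t_off_s = if (is.null(pr)) NA_real_ else pr$t_off_s,
    irrigation_ml_min = if (is.null(config$scene)) NA_real_ else
      config$scene$irrigation_ml_per_min,
    fiber_site = config$fiber_site,
    area_mm2 = if (is.null(result)) NA_real_ else result$area_mm2,
    n_pixels = if (is.null(result)) NA_integer_ else result$n_pixels,
    max_delta_t_C = if (is.null(result)) NA_real_ else result$max_delta_t_C,
    hottest_row = if (is.null(result)) NA_integer_ else
      result$hottest_pixel[1],
    hottest_col = if (is.null(result)) NA_integer_ else
      result$hottest_pixel[2],
    qc_flag = if (config$qc_excluded) config$qc_reason else "ok",
    stringsAsFactors = FALSE)
}

provenance_record <- function(config) {
  scalar <- function(x) if (is.null(x)) NULL else unclass(x)
  list(package = "mrthermodose",
       version = as.character(utils::packageVersion("mrthermodose")),
       run_id = config$run_id, seed = config$seed,
       protocol = scalar(config$protocol),
       acq = scalar(config$acq),
       scene = if (is.null(config$scene)) NULL else {
         s <- unclass(config$scene)
         s$cavity_mask <- which(s$cavity_mask)   # flat indices, column-major
         s$tissue_mask <- which(s$tissue_mask)
         s
       },
       series_dir = config$series_dir,
       dose = scalar(config$dose),
       prf_coeff_ppm_per_C = config$prf_coeff_ppm_per_C,
       noise_sd = config$noise_sd, air_margin_px = config$air_margin_px,
       duration_s = config$duration_s, laser_start_s = config$laser_start_s,
       smooth = config$smooth, smooth_width = config$smooth_width,
       fiber_site = config$fiber_site,
       baseline_temp_C = config$baseline_temp_C,
       qc_excluded = config$qc_excluded, qc_reason = config$qc_reason)
}

#' Run one experiment through the full analysis chain
#'
#' Simulation sources run simulate -> encode -> reconstruct; file sources
#' are read from disk and reconstructed. Both then pass through
#' noise mask -> kidney ROI -> (optional) 3 x 3 smoothing -> CEM43 dose ->
#' critical-area summary. Reruns with an identical config reproduce
#' identical outputs. A `qc_excluded` config is skipped with its reason
#' recorded in the summary row.
#'
#' @param config An [experiment_config()].
#' @return An object of class `experiment_run`: a list with `result`
#'   (a [critical_area()] result, or `NULL` if skipped), `dose`, `temps`
#'   (smoothed), `mask`, `series`, `row` (one summary data frame row) and
#'   `config`. If `config$output_dir` is set, the dose map, a summary CSV
#'   row and a JSON provenance record are written there.
#' @examples
#' cfg <- experiment_config(
#'   protocol = laser_protocol(30, 5, 5, n_applications = 1),
#'   scene = scene_preset("calyx", grid_shape = c(32, 32),
#'                        irrigation_ml_per_min = 10),
#'   duration_s = 20, noise_sd = 0, seed = 7)
#' run <- run_experiment(cfg)
#' run$row$area_mm2
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  if (config$qc_excluded) {
    message(sprintf("run %s skipped (QC): %s", config$run_id,
                    config$qc_reason))
    out <- structure(list(result = NULL, dose = NULL, temps = NULL,
                          mask = NULL, series = NULL,
                          row = summary_row(config, NULL), config = config),
                     class = "experiment_run")
    write_run_artifacts(out)
    return(out)
  }

  if (!is.null(config$series_dir)) {
    series <- read_series(config$series_dir)
    air_roi <- config$air_roi
    kidney_roi <- config$kidney_roi
  } else {
    truth <- simulate_temperature(
      config$protocol, config$scene, config$duration_s,
      frame_interval_s = config$acq$frame_interval_s,
      laser_start_s = config$laser_start_s)
    series <- encode_mr_series(
      truth, config$acq, prf_coeff_ppm_per_C = config$prf_coeff_ppm_per_C,
      noise_sd = config$noise_sd, air_margin_px = config$air_margin_px,
      seed = config$seed)
    air_roi <- if (is.null(config$air_roi))
      border_roi(config$scene$grid_shape, config$air_margin_px)
    else config$air_roi
    kidney_roi <- if (is.null(config$kidney_roi))
      roi_spec(config$scene$cavity_mask | config$scene$tissue_mask)
    else config$kidney_roi
  }

  temps <- reconstruct_delta_t(series, config$prf_coeff_ppm_per_C,
                               baseline_temp_C = config$baseline_temp_C)
  mask <- noise_mask(series, air_roi)
  mask <- apply_roi(mask, kidney_roi)
  if (config$smooth)
    temps <- smooth_temperature(temps, mask, config$smooth_width)
  dose <- cem43(temps, mask, config$dose,
                pixel_area_mm2 = pixel_area(series$acq),
                dt_s = series$acq$frame_interval_s)
  result <- critical_area(dose, temps, mask, config$dose)

  out <- structure(list(result = result, dose = dose, temps = temps,
                        mask = mask, series = series,
                        row = summary_row(config, result), config = config),
                   class = "experiment_run")
  write_run_artifacts(out)
  out
}

write_run_artifacts <- function(run) {
  dir <- run$config$output_dir
  if (is.null(dir)) return(invisible(run))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(run$dose))
    write_dose_map(run$dose,
                   file.path(dir, paste0(run$config$run_id, "_cem43.txt")))
  csv <- file.path(dir, "summary.csv")
  utils::write.table(run$row, csv, sep = ",", row.names = FALSE,
                     col.names = !file.exists(csv), append = file.exists(csv),
                     qmethod = "double")
  jsonlite::write_json(provenance_record(run$config),
                       file.path(dir, paste0(run$config$run_id, "_prov.json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(run)
}

#' @export
print.experiment_run <- function(x, ...) {
  cat(sprintf("Experiment run '%s'\n", x$config$run_id))
  if (is.null(x$result)) cat("  skipped (QC excluded)\n") else print(x$result)
  invisible(x)
}

#' Specify a parameter sweep over the study grid
#'
#' Full factorial of laser powers x pulse protocols x irrigation rates x
#' fiber sites x replicates. Per-cell seeds are derived deterministically
#' from `base_seed`, so partial reruns are stable.
#'
#' @param powers_W Numeric vector of laser powers (study: 14 and 30 W).
#' @param protocols List of [laser_protocol()]s; their `power_watts` is
#'   overridden per grid cell.
#' @param irrigation_rates_ml_min Numeric vector (study: 10, 30, 50, 70,
#'   100 ml/min).
#' @param fiber_sites Character vector of [scene_preset()] names.
#' @param replicates Replicates per cell (study: three to eight).
#' @param base_seed Integer base seed.
#' @param grid_shape Raster size of the preset scenes.
#' @param duration_s Simulated duration per run (`NULL`: per-protocol
#'   default).
#' @param noise_sd Encoder noise level.
#' @param scene_args Extra arguments passed to [scene_preset()].
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(powers_W = c(14, 30),
                       protocols = list(laser_protocol(30, 5, 5),
                                        laser_protocol(30, 5, 10),
                                        laser_protocol(30, 10, 5),
                                        laser_protocol(30, 10, 10),
                                        laser_protocol(30, 20, 0, 1)),
                       irrigation_rates_ml_min = c(10, 30, 50, 70, 100),
                       fiber_sites = c("calyx", "pelvis"),
                       replicates = 3L, base_seed = 1L,
                       grid_shape = c(64L, 64L), duration_s = NULL,
                       noise_sd = 2, scene_args = list()) {
  stopifnot(length(powers_W) >= 1, length(protocols) >= 1,
            length(irrigation_rates_ml_min) >= 1,
            length(fiber_sites) >= 1, replicates >= 1)
  structure(list(powers_W = powers_W, protocols = protocols,
                 irrigation_rates_ml_min = irrigation_rates_ml_min,
                 fiber_sites = fiber_sites,
                 replicates = as.integer(replicates),
                 base_seed = as.integer(base_seed),
                 grid_shape = as.integer(grid_shape),
                 duration_s = duration_s, noise_sd = noise_sd,
                 scene_args = scene_args),
            class = "sweep_spec")
}

# deterministic per-cell seed, kept inside the 32-bit integer range
cell_seed <- function(base_seed, ip, il, ir, is_, rep) {
  as.integer((base_seed + 1000003 * ip + 10007 * il + 211 * ir +
                37 * is_ + rep) %% 2000000000)
}

#' Run a parameter sweep
#'
#' One [run_experiment()] per grid cell and replicate. Failures in a cell
#' are recorded in that row's `qc_flag` and the sweep continues.
#'
#' @param spec A [sweep_spec()].
#' @param output_dir Optional directory; per-run artifacts and the combined
#'   `sweep.csv` are written there.
#' @return A data frame with one summary row per run (columns `run_id`,
#'   `power_W`, `t_on_s`, `t_off_s`, `irrigation_ml_min`, `fiber_site`,
#'   `area_mm2`, `n_pixels`, `max_delta_t_C`, `hottest_row`, `hottest_col`,
#'   `qc_flag`).
#' @seealso [summarize_sweep()] for the pivoted mean +/- SD table.
#' @export
run_sweep <- function(spec, output_dir = NULL) {
  stopifnot(inherits(spec, "sweep_spec"))
  rows <- list()
  for (ip in seq_along(spec$powers_W))
    for (il in seq_along(spec$protocols))
      for (ir in seq_along(spec$irrigation_rates_ml_min))
        for (is_ in seq_along(spec$fiber_sites))
          for (rep_ in seq_len(spec$replicates)) {
            pr0 <- spec$protocols[[il]]
            pr <- laser_protocol(spec$powers_W[ip], pr0$t_on_s, pr0$t_off_s,
                                 pr0$n_applications)
            site <- spec$fiber_sites[is_]
            seed <- cell_seed(spec$base_seed, ip, il, ir, is_, rep_)
            run_id <- sprintf("P%g_L%g_D%g_I%g_%s_r%d",
                              pr$power_watts, pr$t_on_s, pr$t_off_s,
                              spec$irrigation_rates_ml_min[ir], site, rep_)
            row <- tryCatch({
              scene <- do.call(scene_preset, c(
                list(site = site, grid_shape = spec$grid_shape,
                     irrigation_ml_per_min =
                       spec$irrigation_rates_ml_min[ir]),
                spec$scene_args))
              cfg <- experiment_config(
                protocol = pr, scene = scene, noise_sd = spec$noise_sd,
                duration_s = spec$duration_s, seed = seed, run_id = run_id,
                fiber_site = site, output_dir = output_dir)
              run_experiment(cfg)$row
            }, error = function(e) {
              r <- stats::setNames(
                as.data.frame(as.list(rep(NA, length(summary_columns)))),
                summary_columns)
              r$run_id <- run_id
              r$power_W <- pr$power_watts
              r$t_on_s <- pr$t_on_s; r$t_off_s <- pr$t_off_s
              r$irrigation_ml_min <- spec$irrigation_rates_ml_min[ir]
              r$fiber_site <- site
              r$qc_flag <- paste("error:", conditionMessage(e))
              r
            })
            rows[[length(rows) + 1L]] <- row
          }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out, file.path(output_dir, "sweep.csv"),
                     row.names = FALSE)
  }
  out
}

#' Pivoted mean +/- SD critical-area table of a sweep
#'
#' Aggregates the long-format sweep rows into a wide table: one row per
#' power x protocol x site, one pair of columns (mean, SD of the critical
#' area in mm^2) per irrigation rate — the layout of the study's summary
#' table.
#'
#' @param rows Data frame returned by [run_sweep()].
#' @return A data frame with columns `power_W`, `protocol`, `fiber_site`,
#'   then `mean_I<rate>` and `sd_I<rate>` per irrigation rate.
#' @export
summarize_sweep <- function(rows) {
  ok <- rows[rows$qc_flag == "ok" & !is.na(rows$area_mm2), ]
  ok$protocol <- sprintf("%g/%g", ok$t_on_s, ok$t_off_s)
  agg <- stats::aggregate(area_mm2 ~ power_W + protocol + fiber_site +
                            irrigation_ml_min, data = ok,
                          FUN = function(x) c(mean = mean(x), sd = stats::sd(x)))
  flat <- data.frame(agg[1:4], mean = agg$area_mm2[, "mean"],
                     sd = agg$area_mm2[, "sd"])
  rates <- sort(unique(flat$irrigation_ml_min))
  keys <- unique(flat[c("power_W", "protocol", "fiber_site")])
  out <- keys
  for (r in rates) {
    sub <- flat[flat$irrigation_ml_min == r, ]
    idx <- match(interaction(keys$power_W, keys$protocol, keys$fiber_site),
                 interaction(sub$power_W, sub$protocol, sub$fiber_site))
    out[[sprintf("mean_I%g", r)]] <- sub$mean[idx]
    out[[sprintf("sd_I%g", r)]] <- sub$sd[idx]
  }
  rownames(out) <- NULL
  out
}
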