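# End-to-end runs tying the stages together, plus the application config.
# Every constant lives in the config so site/operator recalibration is a
# config swap, not a code change.

#' Application configuration
#'
#' Aggregates every tunable constant of both operating modes. Defaults are
#' the published calibration: detector constants (window 85 samples,
#' per-channel K and floors), calibration factor 1.4735, declination -6.13
#' degrees, the sharpness thresholds, 30 fps video, 20 % frame retention and
#' a 5 m GPS error bound.
#'
#' @param detection A [detection_config()].
#' @param calibration_factor Displacement calibration factor.
#' @param declination Site magnetic declination, degrees.
#' @param projection A [projection_spec()].
#' @param thresholds A [sharpness_thresholds()].
#' @param fps Video frame rate.
#' @param t0_offset Video-to-log start offset, seconds.
#' @param retention Frame retention fraction.
#' @param max_gps_error Worst-case GPS seed error, metres.
#' @param operator Sharpness operator for frame decisions.
#' @param seed Integer seed for any stochastic step.
#' @return An `app_config` list.
#' @export
app_config <- function(detection = detection_config(),
                       calibration_factor = 1.4735,
                       declination = -6.13,
                       projection = projection_spec(),
                       thresholds = sharpness_thresholds(),
                       fps = 30,
                       t0_offset = 0,
                       retention = 0.2,
                       max_gps_error = 5,
                       operator = "laplacian",
                       seed = 1L) {
  stopifnot(calibration_factor > 0, fps > 0, retention > 0, retention <= 1,
            max_gps_error >= 0)
  structure(list(detection = detection, calibration_factor = calibration_factor,
                 declination = declination, projection = projection,
                 thresholds = thresholds, fps = fps, t0_offset = t0_offset,
                 retention = retention, max_gps_error = max_gps_error,
                 operator = operator, seed = as.integer(seed)),
            class = "app_config")
}

#' Write / read an application config as JSON
#'
#' @param config An [app_config()].
#' @param path JSON file path.
#' @return `path` invisibly / an `app_config`.
#' @export
write_app_config <- function(config, path) {
  jsonlite::write_json(unclass_deep(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_app_config
#' @export
read_app_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  det <- raw$detection
  app_config(
    detection = detection_config(M = det$M, K = unlist(det$K),
                                 min_thd = unlist(det$min_thd),
                                 min_segment = det$min_segment),
    calibration_factor = raw$calibration_factor,
    declination = raw$declination,
    projection = do.call(projection_spec, as.list(raw$projection)),
    thresholds = do.call(sharpness_thresholds, as.list(raw$thresholds)),
    fps = raw$fps, t0_offset = raw$t0_offset, retention = raw$retention,
    max_gps_error = raw$max_gps_error, operator = raw$operator,
    seed = raw$seed)
}

unclass_deep <- function(x) {
  if (is.list(x)) return(purrr::map(unclass(x), unclass_deep))
  # named vectors must become JSON objects, not bare arrays
  if (is.atomic(x) && !is.null(names(x))) return(as.list(x))
  if (!is.null(attr(x, "class"))) unclass(x) else x
}

#' Run the navigation pipeline on a log
#'
#' Chains trace reading, static-mask detection, ZUPT/drift kinematics and
#' track accumulation. The GPS seed is the trace's first fix.
#'
#' @param log Path to an NM sensor log, or an [imu_trace()].
#' @param config An [app_config()].
#' @param out_dir Optional directory; when given, writes `track.csv`,
#'   `track.geojson` and `segments.csv` there.
#' @return List with `track` (an `ins_track`), `kinematics`
#'   (a `kinematic_profile`) and `summary` (tibble: segments, total path
#'   length, total calibrated length).
#' @export
run_navigation <- function(log, config = app_config(), out_dir = NULL) {
  trace <- if (inherits(log, "imu_trace")) log else read_imu_trace(log, mode = "NM")
  if (!is_uniform(trace)) trace <- resample_uniform(trace)
  kin <- nav_kinematics(trace, config = config$detection,
                        factor = config$calibration_factor)
  if (nrow(kin$segments) == 0) {
    warn("No movement detected; the track is the GPS seed only.")
  }
  fix <- which(!is.na(trace$lat))
  if (length(fix) == 0) {
    abort(paste("Navigation log has no GPS fix; cannot seed the track.",
                "Record a fix or pass a trace with a manual seed row."))
  }
  seed <- list(lat = trace$lat[fix[1]], lon = trace$lon[fix[1]])
  movements <- tibble(dX = kin$segments$disp_cal_x,
                      dY = kin$segments$disp_cal_y,
                      azimuth = kin$segments$heading)
  track <- accumulate_track(seed, movements, spec = config$projection,
                            declination = config$declination)
  summary <- tibble(
    n_segments = nrow(kin$segments),
    path_length = sum(kin$segments$disp_cal_norm),
    mean_step = if (nrow(kin$segments)) mean(kin$segments$disp_cal_norm) else NA_real_)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(as_tibble(as.data.frame(track)),
                     file.path(out_dir, "track.csv"))
    readr::write_csv(kin$segments, file.path(out_dir, "segments.csv"))
    write_track_geojson(track, file.path(out_dir, "track.geojson"))
  }
  list(track = track, kinematics = kin, summary = summary)
}

#' Run the acquisition-control pipeline on a log plus frames
#'
#' Detects the branch-scan period from the gyroscope log, trims the frame
#' range to the movement, scores the trimmed frames and selects the sharp
#' ones.
#'
#' @param log Path to an ACM sensor log, or an [imu_trace()].
#' @param frames Directory of numbered PNG frames, or a list of frames.
#' @param config An [app_config()].
#' @param out_dir Optional directory; when given, writes `trim.json` and
#'   `selection.csv`.
#' @return List with `period` (`scan_period`), `trim` (frame range tibble)
#'   and `selection` (`frame_selection`). `selection$reacquire` is `TRUE`
#'   when all QC frames are blurred.
#' @export
run_acquisition <- function(log, frames, config = app_config(), out_dir = NULL) {
  trace <- if (inherits(log, "imu_trace")) log else read_imu_trace(log, mode = "ACM")
  if (!is_uniform(trace)) trace <- resample_uniform(trace)
  if (is.character(frames) && length(frames) == 1 && dir.exists(frames)) {
    frames <- as.list(sort(list.files(frames, pattern = "\\.png$",
                                      full.names = TRUE)))
  }
  if (length(frames) == 0) abort("No frames found.")
  period <- detect_scan_period(trace, config$detection)
  trim <- map_to_frames(period, fps = config$fps, t0_offset = config$t0_offset,
                        n_frames = length(frames))
  kept <- frames[(trim$frame_start + 1L):trim$frame_end]
  selection <- select_frames(kept, thresholds = config$thresholds,
                             operator = config$operator,
                             retention = config$retention,
                             frame_offset = trim$frame_start)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      list(t_start = period$t_start, t_end = period$t_end,
           frame_start = trim$frame_start, frame_end = trim$frame_end,
           reacquire = selection$reacquire,
           selected = selection$selected),
      file.path(out_dir, "trim.json"), auto_unbox = TRUE, digits = NA)
    readr::write_csv(tidy(selection), file.path(out_dir, "selection.csv"))
  }
  list(period = period, trim = trim, selection = selection)
}

#' Worst-case georeferencing error budget
#'
#' The dead-reckoned track inherits the full error of its single GPS seed
#' plus the relative error of the inertial displacements, so the worst-case
#' total is their sum: with the published 5 m GPS bound and the 0.15 m
#' calibrated INS error, 5.15 m.
#'
#' @param max_gps_error Worst-case GPS seed error, metres (>= 0).
#' @param ins_relative_error Mean relative INS error, metres (>= 0).
#' @return Total worst-case error, metres.
#' @examples
#' error_budget(5, 0.15)
#' @export
error_budget <- function(max_gps_error = 5, ins_relative_error = 0.15) {
  if (max_gps_error < 0 || ins_relative_error < 0) {
    abort("Error components must be >= 0.")
  }
  max_gps_error + ins_relative_error
}
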