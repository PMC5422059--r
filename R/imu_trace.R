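# Sensor-log container and the on-disk CSV dialect.
#
# A recording is one CSV per file, one header line, columns
#   t,accX,accY,accZ,gyroX,gyroY,gyroZ,yaw,pitch,roll,magX,magY,magZ,lat,lon
# lat/lon are blank except on rows where a GPS fix arrived. In R the trace is
# a tibble with snake_case columns (acc_x, gyro_y, ...) mapped 1:1 to the
# file dialect, carrying attributes dt (nominal sampling step, s), mode
# ("NM" navigation / "ACM" acquisition control) and a free-text label.

TRACE_COLS_FILE <- c("t", "accX", "accY", "accZ", "gyroX", "gyroY", "gyroZ",
                     "yaw", "pitch", "roll", "magX", "magY", "magZ",
                     "lat", "lon")
TRACE_COLS_R <- c("t", "acc_x", "acc_y", "acc_z", "gyro_x", "gyro_y", "gyro_z",
                  "yaw", "pitch", "roll", "mag_x", "mag_y", "mag_z",
                  "lat", "lon")

#' Construct an IMU trace
#'
#' Wraps a data frame of time-stamped smartphone sensor samples into an
#' `imu_trace`: a tibble with columns `t` (seconds from recording start),
#' `acc_x/acc_y/acc_z` (gravity-removed linear acceleration, m/s^2, device
#' axes), `gyro_x/gyro_y/gyro_z` (angular velocity, rad/s), `yaw/pitch/roll`
#' (degrees; yaw is the azimuth clockwise from magnetic north),
#' `mag_x/mag_y/mag_z` (magnetometer, uT) and optional `lat`/`lon` (WGS84
#' decimal degrees, `NA` where no GPS fix arrived).
#'
#' @param data Data frame with at least column `t`; missing sensor columns are
#'   filled with zeros, missing `lat`/`lon` with `NA`.
#' @param dt Nominal sampling step in seconds (default 0.01, i.e. 100 Hz).
#' @param mode `"NM"` (navigation) or `"ACM"` (acquisition control).
#' @param label Free-text identifier of the parcel or branch.
#' @return An `imu_trace` tibble.
#' @examples
#' imu_trace(data.frame(t = seq(0, 0.05, by = 0.01), acc_y = 0.1), mode = "NM")
#' @export
imu_trace <- function(data, dt = 0.01, mode = c("NM", "ACM"), label = "") {
  mode <- match.arg(mode)
  if (!is.data.frame(data) || !"t" %in% names(data)) {
    abort("`data` must be a data frame with a column `t`.")
  }
  out <- as_tibble(data)
  for (col in setdiff(TRACE_COLS_R, c("t", "lat", "lon"))) {
    if (is.null(out[[col]])) out[[col]] <- 0
  }
  for (col in c("lat", "lon")) {
    if (is.null(out[[col]])) out[[col]] <- NA_real_
  }
  out <- out[TRACE_COLS_R]
  if (nrow(out) > 0) {
    if (anyNA(out$t)) abort("Timestamps must not be missing.")
    if (any(out$t < 0)) abort("Timestamps must be >= 0 seconds from log start.")
    if (nrow(out) > 1 && any(diff(out$t) <= 0)) {
      abort("Timestamps must be strictly increasing.")
    }
    if (xor(anyNA(out$lat), anyNA(out$lon)) ||
        !identical(which(is.na(out$lat)), which(is.na(out$lon)))) {
      abort("`lat` and `lon` must be present or absent together on each row.")
    }
    out$yaw <- wrap_degrees(out$yaw)
  }
  structure(out,
            class = c("imu_trace", class(tibble())),
            dt = dt, mode = mode, label = label)
}

trace_dt <- function(trace) attr(trace, "dt")
trace_mode <- function(trace) attr(trace, "mode")

#' @export
print.imu_trace <- function(x, ...) {
  cat(sprintf("<imu_trace> mode=%s dt=%gs samples=%d gps_fixes=%d label='%s'\n",
              trace_mode(x), trace_dt(x), nrow(x), sum(!is.na(x$lat)),
              attr(x, "label")))
  NextMethod()
}

#' Is a trace uniformly sampled?
#'
#' A trace is uniform when every timestamp step is within half the nominal
#' step of `dt`.
#'
#' @param trace An [imu_trace()].
#' @return Logical scalar.
#' @export
is_uniform <- function(trace) {
  if (nrow(trace) < 2) return(TRUE)
  all(abs(diff(trace$t) - trace_dt(trace)) <= 0.5 * trace_dt(trace))
}

#' Read a sensor log
#'
#' Parses the one-file-per-recording CSV dialect (header
#' `t,accX,...,lat,lon`; blank `lat`/`lon` where no GPS fix exists) into an
#' [imu_trace()]. Timestamps must be strictly increasing; navigation-mode
#' traces are expected to carry at least one GPS fix (a warning is raised
#' otherwise so a manual seed can be supplied downstream).
#'
#' @param path Path to the CSV log.
#' @param mode `"NM"` or `"ACM"`.
#' @param dt Nominal sampling step, seconds.
#' @param label Optional label; defaults to the file name.
#' @return An `imu_trace`.
#' @export
read_imu_trace <- function(path, mode = c("NM", "ACM"), dt = 0.01,
                           label = NULL) {
  mode <- match.arg(mode)
  if (!file.exists(path)) abort(sprintf("Sensor log '%s' does not exist.", path))
  dat <- suppressWarnings(
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()),
                    na = c("", "NA"), progress = FALSE))
  probs <- readr::problems(dat)
  if (nrow(probs) > 0) {
    # problems() reports 1-based file lines including the header
    abort(sprintf("Malformed sensor log '%s': parse failure at line %d (expected %s).",
                  path, probs$row[1], probs$expected[1]))
  }
  if (nrow(dat) == 0) abort(sprintf("Sensor log '%s' contains no samples.", path))
  missing_cols <- setdiff(TRACE_COLS_FILE, names(dat))
  if (length(missing_cols) > 0) {
    abort(sprintf("Sensor log '%s' lacks column(s): %s.", path,
                  paste(missing_cols, collapse = ", ")))
  }
  names(dat) <- TRACE_COLS_R[match(names(dat), TRACE_COLS_FILE)]
  out <- imu_trace(dat, dt = dt, mode = mode,
                   label = label %||% basename(path))
  if (mode == "NM" && all(is.na(out$lat))) {
    warn("Navigation-mode trace has no GPS fix; supply a manual seed for georeferencing.")
  }
  out
}

#' Write a sensor log
#'
#' Inverse of [read_imu_trace()]: emits the documented CSV dialect at full
#' double precision so that a write/read round trip reproduces every field.
#'
#' @param trace An [imu_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_imu_trace <- function(trace, path) {
  stopifnot(inherits(trace, "imu_trace"))
  out <- as_tibble(as.data.frame(trace))[TRACE_COLS_R]
  names(out) <- TRACE_COLS_FILE
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Resample a trace onto a uniform grid
#'
#' Field logs jitter around the nominal 10 ms step; downstream integration
#' assumes uniform sampling. Continuous channels are linearly interpolated
#' onto `seq(t[1], t[n], by = dt)`; orientation angles are interpolated on
#' the circle (shortest arc, so yaw 359 -> 1 passes through 0); GPS fixes are
#' snapped to the nearest grid sample.
#'
#' @param trace An [imu_trace()] with at least 2 samples.
#' @param dt Target sampling step, seconds (> 0); defaults to the trace's
#'   nominal step.
#' @return A uniform `imu_trace`. First and last timestamps are preserved
#'   (the final step may be shorter than `dt` if the span is not a multiple).
#' @export
resample_uniform <- function(trace, dt = trace_dt(trace)) {
  stopifnot(inherits(trace, "imu_trace"))
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) abort("`dt` must be a positive scalar.")
  if (nrow(trace) < 2) abort("Resampling needs at least 2 samples.")
  t_in <- trace$t
  grid <- seq(t_in[1], t_in[length(t_in)], by = dt)
  if (tail(grid, 1) < t_in[length(t_in)] - 1e-9) {
    grid <- c(grid, t_in[length(t_in)])
  }
  linear_cols <- c("acc_x", "acc_y", "acc_z", "gyro_x", "gyro_y", "gyro_z",
                   "mag_x", "mag_y", "mag_z")
  out <- tibble(t = grid)
  for (col in linear_cols) {
    out[[col]] <- stats::approx(t_in, trace[[col]], xout = grid, rule = 2)$y
  }
  out$yaw <- interp_circular(t_in, trace$yaw, grid, wrap = "pos")
  for (col in c("pitch", "roll")) {
    out[[col]] <- interp_circular(t_in, trace[[col]], grid, wrap = "sym")
  }
  out$lat <- NA_real_
  out$lon <- NA_real_
  fix_rows <- which(!is.na(trace$lat))
  for (i in fix_rows) {
    j <- which.min(abs(grid - t_in[i]))
    out$lat[j] <- trace$lat[i]
    out$lon[j] <- trace$lon[i]
  }
  imu_trace(out, dt = dt, mode = trace_mode(trace), label = attr(trace, "label"))
}
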