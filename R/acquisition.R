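# Acquisition-control mode: locate the single branch-scan movement period in
# a gyroscope trace, map it onto video frame indexes, classify scan speed.

#' Detect the branch-scan period of an acquisition-control trace
#'
#' Builds the angular-velocity static mask and returns the longest movement
#' segment as the scan (the acquisition protocol records one branch per
#' file). Additional shorter segments are reported as a warning; a trace
#' without any movement segment is an error instructing re-acquisition.
#'
#' @param trace A uniform ACM [imu_trace()].
#' @param config A [detection_config()].
#' @return A `scan_period`: tibble row with `t_start`, `t_end`, `duration`
#'   (log seconds) plus attributes carrying the full mask.
#' @export
detect_scan_period <- function(trace, config = detection_config()) {
  stopifnot(inherits(trace, "imu_trace"))
  mask <- build_mask(trace, config, mode = "ACM")
  segs <- mask$segments
  if (nrow(segs) == 0) {
    abort(paste("No scan movement detected in the trace; re-acquire the",
                "branch video."), class = "branchnav_no_scan")
  }
  if (nrow(segs) > 1) {
    warn(sprintf(
      "%d movement segments detected; keeping the longest (%.2f s) as the scan.",
      nrow(segs), max(segs$duration)))
  }
  best <- segs[which.max(segs$duration), ]
  out <- tibble(t_start = best$t_start, t_end = best$t_end,
                duration = best$duration)
  structure(out, class = c("scan_period", class(tibble())), mask = mask)
}

#' Map a scan period to video frame indexes
#'
#' Frame indexes are half-open `[frame_start, frame_end)`, counted from 0 at
#' the start of the video: `round((t - t0_offset) * fps)`, clipped to the
#' video length.
#'
#' @param period A `scan_period` (or any list with `t_start`, `t_end`).
#' @param fps Frames per second of the video (> 0, nominal 30).
#' @param t0_offset Seconds between video start and log start (0 when both
#'   are started by the same button press).
#' @param n_frames Total frame count of the video, used for clipping
#'   (`Inf` to skip).
#' @return Tibble with `frame_start`, `frame_end` (half-open) and `n_kept`.
#' @examples
#' map_to_frames(list(t_start = 2, t_end = 17), fps = 30)  # 450 frames
#' @export
map_to_frames <- function(period, fps = 30, t0_offset = 0, n_frames = Inf) {
  if (!is.numeric(fps) || fps <= 0) abort("`fps` must be > 0.")
  f0 <- round((period$t_start[1] - t0_offset) * fps)
  f1 <- round((period$t_end[1] - t0_offset) * fps)
  f0 <- max(0, min(f0, n_frames))
  f1 <- max(0, min(f1, n_frames))
  if (f1 <= f0) {
    abort("Scan period lies entirely outside the video.")
  }
  tibble(frame_start = as.integer(f0), frame_end = as.integer(f1),
         n_kept = as.integer(f1 - f0))
}

#' Classify a branch-scan velocity
#'
#' Speed classes for handset translation along the branch: `low` below
#' 5 cm/s (the only class at which frames stay sharp), `medium` 5-10 cm/s
#' inclusive, `high` above 10 cm/s.
#'
#' @param mean_speed Mean scan speed, cm/s (>= 0).
#' @return Character vector: `"low"`, `"medium"` or `"high"`.
#' @examples
#' classify_velocity(c(3, 5, 12))
#' @export
classify_velocity <- function(mean_speed) {
  if (any(!is.finite(mean_speed)) || any(mean_speed < 0)) {
    abort("`mean_speed` must be nonnegative.")
  }
  dplyr::case_when(mean_speed < 5 ~ "low",
                   mean_speed <= 10 ~ "medium",
                   TRUE ~ "high")
}
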