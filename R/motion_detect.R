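# Static/movement segmentation of an inertial signal.
#
# The detector compares a block-wise local-maxima envelope of the inertial
# signal magnitude against a dynamic threshold mean + K*sd with a per-channel
# floor measured on a steady, hand-held device. Navigation mode watches the
# two horizontal linear-acceleration axes; acquisition-control mode watches
# the angular velocity about the device's Y axis.

#' Detection configuration
#'
#' Constants of the static-period detector. `K` and `min_thd` are per-channel:
#' `acc_x` and `acc_y` (linear acceleration, m/s^2) drive navigation mode,
#' `gyro_y` (angular velocity, rad/s) drives acquisition-control mode. The
#' defaults are the published operator calibration: window `M` of 85 samples
#' (0.85 s at 100 Hz), K = 1.8 / 0.44 / 1.8 and magnitude floors
#' 0.15 / 0.15 / 0.05 for acc_x / acc_y / gyro_y. The floor is the largest
#' magnitude observed while the operator holds the device without moving, so
#' it should be re-measured per operator.
#'
#' @param M Samples per local-maxima window (>= 1).
#' @param K Named adjustment factors, one per channel.
#' @param min_thd Named magnitude floors, one per channel.
#' @param min_segment Seconds; movement runs shorter than this are relabelled
#'   static (debounce against single-window spikes).
#' @return A list of class `detection_config`.
#' @examples
#' detection_config()
#' @export
detection_config <- function(M = 85L,
                             K = c(acc_x = 1.8, acc_y = 0.44, gyro_y = 1.8),
                             min_thd = c(acc_x = 0.15, acc_y = 0.15, gyro_y = 0.05),
                             min_segment = 0.3) {
  M <- as.integer(M)
  if (is.na(M) || M < 1) abort("`M` must be a positive integer.")
  if (any(K < 0) || any(min_thd < 0)) abort("`K` and `min_thd` must be >= 0.")
  for (ch in c("acc_x", "acc_y", "gyro_y")) {
    if (is.na(K[ch]) || is.na(min_thd[ch])) {
      abort(sprintf("`K` and `min_thd` must both name channel '%s'.", ch))
    }
  }
  structure(list(M = M, K = K, min_thd = min_thd, min_segment = min_segment),
            class = "detection_config")
}

#' Magnitude of an inertial signal
#'
#' Element-wise `sqrt(x^2)`, i.e. the absolute value of the channel. Applied
#' to linear acceleration (navigation) or angular velocity (acquisition
#' control) before envelope extraction.
#'
#' @param x Numeric series.
#' @return Nonnegative series of the same length.
#' @export
signal_magnitude <- function(x) {
  if (length(x) == 0) abort("`x` must be non-empty.")
  sqrt(x^2)
}

#' Block-wise local-maxima envelope
#'
#' Splits the magnitude series into consecutive blocks of `M` samples and
#' assigns every sample in a block the maximum magnitude of that block (the
#' final partial block uses its own maximum). The result is piecewise
#' constant and bounds the magnitude from above.
#'
#' @param mag Nonnegative magnitude series.
#' @param M Block size in samples.
#' @return Envelope series, same length as `mag`.
#' @examples
#' local_max_envelope(c(1, 5, 2, 4, 1, 0), M = 3)
#' @export
local_max_envelope <- function(mag, M) {
  M <- as.integer(M)
  if (is.na(M) || M < 1) abort("`M` must be >= 1.")
  n <- length(mag)
  if (n == 0) return(numeric(0))
  block <- (seq_len(n) - 1L) %/% M
  blockmax <- vapply(split(mag, block), max, numeric(1))
  as.numeric(blockmax[block + 1L])
}

#' Dynamic detection threshold
#'
#' `max(mean(mag) + K * sd(mag), min_thd)`, with the standard deviation taken
#' with denominator n over the whole recording. The floor `min_thd` is the
#' hand-held idle magnitude ceiling, which binds when a recording is almost
#' entirely static.
#'
#' @param mag Magnitude series.
#' @param K Adjustment factor for the channel.
#' @param min_thd Magnitude floor for the channel.
#' @return Scalar threshold.
#' @export
dynamic_threshold <- function(mag, K, min_thd) {
  if (length(mag) == 0) abort("`mag` must be non-empty.")
  mu <- mean(mag)
  sigma <- sqrt(mean((mag - mu)^2))
  max(mu + K * sigma, min_thd)
}

mode_channels <- function(mode) {
  switch(mode, NM = c("acc_x", "acc_y"), ACM = "gyro_y",
         abort(sprintf("Unknown mode '%s'.", mode)))
}

# Maximal runs of TRUE as half-open [i_start, i_end) index pairs.
runs_true <- function(moving) {
  if (!any(moving)) {
    return(tibble(i_start = integer(0), i_end = integer(0)))
  }
  r <- rle(moving)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble(i_start = starts[keep], i_end = ends[keep] + 1L)
}

#' Build the static/movement mask of a trace
#'
#' Labels every sample of a uniformly sampled trace as moving or static. A
#' sample is moving when, on any of the mode's channels, the local-maxima
#' envelope of the channel magnitude exceeds that channel's dynamic
#' threshold. Movement runs shorter than `min_segment` seconds are relabelled
#' static, and the surviving maximal runs become the movement segments. The
#' moving mask multiplies the acceleration downstream, which forces the
#' sensor signal to zero whenever the device is idle.
#'
#' @param trace A uniform [imu_trace()].
#' @param config A [detection_config()].
#' @param mode Channel set to use; defaults to the trace's mode (`"NM"`:
#'   acc_x, acc_y; `"ACM"`: gyro_y).
#' @return A `static_mask`: list with `moving` (logical per sample),
#'   `segments` (tibble `segment_id`, `i_start`, `i_end` half-open,
#'   `t_start`, `t_end`, `duration`), `thd_used` (named per-channel
#'   thresholds), plus the sampling step and channels used.
#' @export
build_mask <- function(trace, config = detection_config(), mode = trace_mode(trace)) {
  stopifnot(inherits(trace, "imu_trace"), inherits(config, "detection_config"))
  if (!is_uniform(trace)) {
    abort("`trace` is not uniformly sampled; call resample_uniform() first.")
  }
  if (nrow(trace) == 0) abort("`trace` has no samples.")
  channels <- mode_channels(mode)
  dt <- trace_dt(trace)
  per_channel <- purrr::map(channels, function(ch) {
    mag <- signal_magnitude(trace[[ch]])
    thd <- dynamic_threshold(mag, config$K[[ch]], config$min_thd[[ch]])
    list(moving = local_max_envelope(mag, config$M) > thd, thd = thd)
  })
  moving <- purrr::reduce(purrr::map(per_channel, "moving"), `|`)
  thd_used <- setNames(purrr::map_dbl(per_channel, "thd"), channels)

  # debounce: drop movement runs shorter than min_segment
  min_len <- ceiling(config$min_segment / dt)
  runs <- runs_true(moving)
  short <- runs[(runs$i_end - runs$i_start) < min_len, ]
  if (nrow(short) > 0) {
    for (k in seq_len(nrow(short))) {
      moving[short$i_start[k]:(short$i_end[k] - 1L)] <- FALSE
    }
  }
  segs <- runs_true(moving)
  segs <- dplyr::mutate(segs,
    segment_id = dplyr::row_number(),
    t_start = trace$t[.data$i_start],
    t_end = trace$t[1] + (.data$i_end - 1L) * dt,
    duration = (.data$i_end - .data$i_start) * dt,
    .before = 1L)
  structure(list(moving = moving, segments = segs, thd_used = thd_used,
                 dt = dt, channels = channels, n = nrow(trace)),
            class = "static_mask")
}

#' @export
print.static_mask <- function(x, ...) {
  cat(sprintf("<static_mask> %d samples, %d movement segment(s), channels: %s\n",
              x$n, nrow(x$segments), paste(x$channels, collapse = ", ")))
  cat(sprintf("thresholds: %s\n",
              paste(sprintf("%s=%.4g", names(x$thd_used), x$thd_used), collapse = ", ")))
  if (nrow(x$segments) > 0) print(x$segments)
  invisible(x)
}

#' @rdname build_mask
#' @param x A `static_mask`.
#' @param ... Unused.
#' @export
tidy.static_mask <- function(x, ...) x$segments

#' Plot a static mask over the channel magnitudes
#'
#' @param object A `static_mask`.
#' @param trace The trace the mask was built from.
#' @param ... Unused.
#' @return A ggplot object: per-channel magnitude with shaded movement
#'   segments and the applied thresholds.
#' @export
autoplot.static_mask <- function(object, trace, ...) {
  stopifnot(inherits(trace, "imu_trace"))
  long <- tidyr::pivot_longer(
    dplyr::select(as_tibble(as.data.frame(trace)), "t", dplyr::all_of(object$channels)),
    -"t", names_to = "channel", values_to = "value")
  long$value <- abs(long$value)
  thd <- tibble(channel = names(object$thd_used), thd = unname(object$thd_used))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value))
  if (nrow(object$segments) > 0) {
    p <- p + ggplot2::geom_rect(
      data = object$segments,
      ggplot2::aes(xmin = .data$t_start, xmax = .data$t_end, ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "steelblue", alpha = 0.15)
  }
  p +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::geom_hline(data = thd, ggplot2::aes(yintercept = .data$thd),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time [s]", y = "|signal| magnitude",
                  title = "Movement segments vs. detection thresholds")
}
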