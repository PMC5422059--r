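# Navigation-mode kinematics: ZUPT velocity integration, straight-line drift
# compensation per movement segment, displacement integration and the
# calibration regression.

#' Integrate acceleration to velocity with zero-velocity updates
#'
#' Rectangular integration `v[i] = v[i-1] + a[i] * dt`, with the acceleration
#' pre-multiplied by the moving mask. Velocity is forced to zero on every
#' static sample (the zero-velocity update) and the integration restarts from
#' zero at each movement segment start, so integration noise cannot
#' accumulate across idle periods.
#'
#' @param trace A uniform [imu_trace()].
#' @param mask The [build_mask()] result for the same trace.
#' @param axes Acceleration channels to integrate (default the two horizontal
#'   device axes used for navigation).
#' @return Tibble with `t` and one `v_<axis>` column per axis (m/s).
#' @export
integrate_velocity <- function(trace, mask, axes = c("acc_x", "acc_y")) {
  stopifnot(inherits(trace, "imu_trace"), inherits(mask, "static_mask"))
  if (length(mask$moving) != nrow(trace)) {
    abort("`mask` and `trace` have different lengths.")
  }
  dt <- trace_dt(trace)
  out <- tibble(t = trace$t)
  for (ax in axes) {
    v <- numeric(nrow(trace))
    segs <- mask$segments
    for (k in seq_len(nrow(segs))) {
      idx <- segs$i_start[k]:(segs$i_end[k] - 1L)
      v[idx] <- cumsum(trace[[ax]][idx]) * dt
    }
    out[[paste0("v_", sub("^acc_", "", ax))]] <- v
  }
  out
}

#' Straight-line drift compensation of a segment velocity
#'
#' Integration error leaves a spurious nonzero velocity at the end of a
#' movement segment even though the device has stopped. The drift is modelled
#' as the straight line through zero at the segment start and the spurious
#' final velocity at the segment end, and subtracted, which forces the
#' compensated end-of-segment velocity to zero exactly. Negative compensated
#' velocities that this can produce are deliberately kept; the systematic
#' under-measurement they cause is absorbed by the global calibration factor.
#'
#' @param v Velocity series of the whole trace (one axis).
#' @param segment One row of a mask's `segments` tibble (`i_start`, `i_end`,
#'   `duration`).
#' @param dt Sampling step, seconds.
#' @return List with `v_comp` (full-length series, compensated inside the
#'   segment) and `slope` (drift rate m, m/s^2).
#' @export
compensate_drift <- function(v, segment, dt) {
  i0 <- segment$i_start[1]
  i1 <- segment$i_end[1]
  duration <- segment$duration[1]
  if (!is.finite(duration) || duration <= 0) abort("Zero-duration segment.")
  idx <- i0:(i1 - 1L)
  v_end <- v[i1 - 1L]
  slope <- v_end / duration
  elapsed <- seq_along(idx) * dt  # time since segment start at each sample
  v_comp <- v
  v_comp[idx] <- v[idx] - slope * elapsed
  list(v_comp = v_comp, slope = slope)
}

#' Integrate a compensated segment velocity to displacement
#'
#' Rectangular integral of the compensated velocity over one movement
#' segment, then scaled by the calibration factor.
#'
#' @param v_comp Compensated velocity series (full trace, one axis).
#' @param segment One row of a `segments` tibble.
#' @param dt Sampling step, seconds.
#' @param factor Calibration factor (default the published 1.4735).
#' @return List with `disp` (raw, m) and `disp_cal` (= factor * disp, m).
#' @export
integrate_displacement <- function(v_comp, segment, dt, factor = 1.4735) {
  idx <- segment$i_start[1]:(segment$i_end[1] - 1L)
  disp <- sum(v_comp[idx]) * dt
  list(disp = disp, disp_cal = factor * disp)
}

#' Full per-segment kinematic profile of a navigation trace
#'
#' Chains [integrate_velocity()], [compensate_drift()] and
#' [integrate_displacement()] over every movement segment of a trace and
#' collects, per segment and axis, the drift slope and the raw and calibrated
#' displacements, together with the per-sample velocity stages.
#'
#' @param trace A uniform navigation-mode [imu_trace()].
#' @param mask [build_mask()] result; computed from `trace` when missing.
#' @param config [detection_config()] used if the mask must be built.
#' @param factor Calibration factor.
#' @return A `kinematic_profile`: list with `velocity` (tibble `t`,
#'   `v_zupt_x/y`, `v_comp_x/y`), `segments` (tibble adding `slope_x/y`,
#'   `disp_x/y`, `disp_cal_x/y`, `disp_norm`, `disp_cal_norm`, `heading`),
#'   `factor` and the mask. `heading` is the circular mean yaw over each
#'   segment's samples.
#' @export
nav_kinematics <- function(trace, mask = NULL, config = detection_config(),
                           factor = 1.4735) {
  stopifnot(inherits(trace, "imu_trace"))
  mask <- mask %||% build_mask(trace, config, mode = "NM")
  dt <- trace_dt(trace)
  vel <- integrate_velocity(trace, mask)
  segs <- mask$segments
  comp_x <- vel$v_x
  comp_y <- vel$v_y
  empty_extra <- tibble(slope_x = double(0), slope_y = double(0),
                        disp_x = double(0), disp_y = double(0),
                        disp_cal_x = double(0), disp_cal_y = double(0),
                        disp_norm = double(0), disp_cal_norm = double(0),
                        heading = double(0))
  extra <- purrr::map_dfr(seq_len(nrow(segs)), function(k) {
    seg <- segs[k, ]
    cx <- compensate_drift(vel$v_x, seg, dt)
    cy <- compensate_drift(vel$v_y, seg, dt)
    idx <- seg$i_start:(seg$i_end - 1L)
    comp_x[idx] <<- cx$v_comp[idx]
    comp_y[idx] <<- cy$v_comp[idx]
    dx <- integrate_displacement(cx$v_comp, seg, dt, factor)
    dy <- integrate_displacement(cy$v_comp, seg, dt, factor)
    tibble(slope_x = cx$slope, slope_y = cy$slope,
           disp_x = dx$disp, disp_y = dy$disp,
           disp_cal_x = dx$disp_cal, disp_cal_y = dy$disp_cal,
           disp_norm = sqrt(dx$disp^2 + dy$disp^2),
           disp_cal_norm = factor * sqrt(dx$disp^2 + dy$disp^2),
           heading = circular_mean(trace$yaw[idx]))
  })
  if (nrow(segs) == 0) extra <- empty_extra
  segments <- dplyr::bind_cols(segs, extra)
  velocity <- tibble(t = vel$t,
                     v_zupt_x = vel$v_x, v_zupt_y = vel$v_y,
                     v_comp_x = comp_x, v_comp_y = comp_y)
  structure(list(velocity = velocity, segments = segments,
                 factor = factor, mask = mask),
            class = "kinematic_profile")
}

#' @export
print.kinematic_profile <- function(x, ...) {
  cat(sprintf("<kinematic_profile> %d segment(s), calibration factor %.4f\n",
              nrow(x$segments), x$factor))
  print(dplyr::select(x$segments, "segment_id", "t_start", "t_end",
                      "disp_cal_x", "disp_cal_y", "disp_cal_norm", "heading"))
  invisible(x)
}

#' @rdname nav_kinematics
#' @param x A `kinematic_profile`.
#' @param ... Unused.
#' @export
tidy.kinematic_profile <- function(x, ...) x$segments

#' Plot velocity stages of a kinematic profile
#'
#' @param object A `kinematic_profile`.
#' @param ... Unused.
#' @return A ggplot of ZUPT-zeroed and drift-compensated velocity per axis.
#' @export
autoplot.kinematic_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(object$velocity, -"t",
                              names_to = c("stage", "axis"),
                              names_pattern = "v_(zupt|comp)_([xy])",
                              values_to = "v")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$v, colour = .data$stage)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~axis, ncol = 1) +
    ggplot2::labs(x = "time [s]", y = "velocity [m/s]", colour = NULL,
                  title = "ZUPT and drift-compensated velocity")
}

#' Fit the displacement calibration factor
#'
#' Least-squares regression through the origin of real displacement on the
#' displacement estimated by the inertial pipeline. The systematic
#' under-measurement of the drift-compensated integration at walking speed is
#' captured by this single coefficient (published value 1.4735 with R^2 0.98
#' and a zero intercept).
#'
#' @param data Data frame with columns `real` and `estimated` (metres), one
#'   row per movement; at least two rows, estimates not all zero.
#' @return An `ins_calibration` object: `factor`, `r2` (through-origin
#'   coefficient of determination), `residuals`, `n`.
#' @examples
#' fit_calibration(data.frame(real = c(1, 2, 3), estimated = c(1, 2, 3) / 1.4735))
#' @export
fit_calibration <- function(data) {
  if (!all(c("real", "estimated") %in% names(data))) {
    abort("`data` needs columns `real` and `estimated`.")
  }
  data <- as_tibble(data)
  if (nrow(data) < 2) abort("Calibration needs at least 2 displacement pairs.")
  if (all(data$estimated == 0)) abort("All estimated displacements are zero.")
  fit <- stats::lm(real ~ 0 + estimated, data = data)
  # suppressWarnings: summary.lm warns on exactly collinear (noise-free) input
  structure(list(factor = unname(stats::coef(fit)[1]),
                 r2 = suppressWarnings(summary(fit)$r.squared),
                 residuals = unname(stats::residuals(fit)),
                 n = nrow(data)),
            class = "ins_calibration")
}

#' Validate a calibration factor on held-out movements
#'
#' Applies `factor` to the estimated displacements and regresses real on
#' calibrated values (through the origin). A slope of 1 means the calibrated
#' system neither over- nor under-estimates displacement.
#'
#' @param data Data frame with columns `real` and `estimated` (raw, metres).
#' @param factor Calibration factor to validate.
#' @return Tibble with `slope`, `r2`, `mean_abs_error` (m), `n`.
#' @export
validate_calibration <- function(data, factor) {
  data <- as_tibble(data)
  data$calibrated <- factor * data$estimated
  fit <- stats::lm(real ~ 0 + calibrated, data = data)
  tibble(slope = unname(stats::coef(fit)[1]),
         r2 = suppressWarnings(summary(fit)$r.squared),
         mean_abs_error = mean(abs(data$real - data$calibrated)),
         n = nrow(data))
}

#' @export
print.ins_calibration <- function(x, ...) {
  cat(sprintf("<ins_calibration> factor %.4f (R^2 = %.4f, n = %d, through origin)\n",
              x$factor, x$r2, x$n))
  invisible(x)
}

#' @rdname fit_calibration
#' @param x An `ins_calibration`.
#' @param ... Unused.
#' @export
tidy.ins_calibration <- function(x, ...) {
  tibble(term = "estimated", estimate = x$factor)
}

#' @rdname fit_calibration
#' @export
glance.ins_calibration <- function(x, ...) {
  tibble(factor = x$factor, r.squared = x$r2, nobs = x$n,
         sigma = sqrt(mean(x$residuals^2)))
}
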