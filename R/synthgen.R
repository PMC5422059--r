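# Synthetic study data: hand-carried walking traces, low-speed branch scans
# and branch-like images, each with exact ground truth. The generators are
# pure functions of their spec (bitwise reproducible per seed) and emulate
# the published acquisition conditions: 100 Hz logs, steps of 0.5-3.75 m at
# ~0.44 m/s, idle acceleration excursions within +-10 mg, per-trace
# accelerometer bias within +-1 mg, a sensor sensitivity deficit equal to
# the reciprocal of the published calibration factor, and 15 s branch scans.

#' Walking-trace specification
#'
#' One navigation-mode recording: the operator stands idle, walks one or
#' more straight steps, and pauses between them. Velocity per step is a
#' trapezoid (20 % ramps) with a windowed gait oscillation superimposed, so
#' acceleration is large at step boundaries, oscillates at the step cadence
#' during the plateau, and integrates back to zero velocity at the stop. The
#' accelerometer reports `accel_sensitivity` times the true acceleration
#' (the documented under-measurement recovered by the calibration factor)
#' plus white noise and a constant per-trace bias.
#'
#' @param step_lengths Step lengths in metres (default the survey grid
#'   spacings 0.5-3.75 m).
#' @param speed Walking speed, m/s (default 0.44, the published median).
#' @param headings Heading per step, degrees clockwise from magnetic north
#'   (recycled to the number of steps).
#' @param idle_gap Idle seconds before, between and after steps.
#' @param noise_idle Idle acceleration excursion bound, m/s^2 (default
#'   0.098 = 10 mg); white noise sd is a third of this so excursions stay in
#'   band.
#' @param accel_sensitivity Dimensionless sensor gain (default 1/1.4735).
#' @param gait_amp Gait velocity oscillation amplitude, m/s.
#' @param gait_freq Step cadence, Hz.
#' @param gps_error Magnitude bound of the seed GPS error, metres (uniform
#'   direction, magnitude uniform in [0, gps_error]).
#' @param origin Named vector `c(lat = , lon = )`: true WGS84 start point.
#' @param declination Site magnetic declination, degrees (the generated yaw
#'   is magnetic, i.e. geographic heading plus declination... corrected back
#'   by the pipeline).
#' @param seed Integer seed.
#' @return A `walk_spec` list.
#' @export
walk_spec <- function(step_lengths = c(0.5, 0.75, 1, 1.5, 2.25, 3, 3.75),
                      speed = 0.44,
                      headings = 0,
                      idle_gap = 2,
                      noise_idle = 0.098,
                      accel_sensitivity = 1 / 1.4735,
                      gait_amp = 0.08,
                      gait_freq = 1.3,
                      gps_error = 0,
                      origin = c(lat = 5.0703, lon = -75.5138),
                      declination = -6.13,
                      seed = 1L) {
  stopifnot(all(step_lengths > 0), speed > 0, accel_sensitivity > 0,
            idle_gap >= 0, noise_idle >= 0, gps_error >= 0)
  structure(list(step_lengths = step_lengths, speed = speed,
                 headings = rep(headings, length.out = length(step_lengths)),
                 idle_gap = idle_gap, noise_idle = noise_idle,
                 accel_sensitivity = accel_sensitivity,
                 gait_amp = gait_amp, gait_freq = gait_freq,
                 gps_error = gps_error, origin = origin,
                 declination = declination, seed = as.integer(seed)),
            class = "walk_spec")
}

# True velocity profile of one step: trapezoid with `ramp` fractional ramps
# plus a gait oscillation windowed by the same ramps so it vanishes at both
# ends. Sampled at the left edge of each dt interval, consistent with
# rectangular integration.
step_velocity <- function(L, speed, gait_amp, gait_freq, dt, ramp = 0.2) {
  duration <- L / speed
  n <- max(2L, round(duration / dt))
  tt <- (seq_len(n) - 1L) * dt
  vp <- speed / (1 - ramp)  # plateau velocity giving mean `speed`
  tr <- ramp * duration
  env <- pmin(1, pmin(tt / tr, (duration - tt) / tr))
  env <- pmax(env, 0)
  v <- vp * env + gait_amp * sinpi(2 * gait_freq * tt) * env
  v * (L / (sum(v) * dt))  # normalise so the discrete integral is exactly L
}

#' Generate a navigation-mode walking trace
#'
#' Builds the true per-axis velocity of the whole recording (movement along
#' the device Y axis, headings on the yaw channel), differentiates it to the
#' acceleration the sensor would report (scaled by the sensitivity, plus
#' bias and noise), and returns the 100 Hz trace together with exact ground
#' truth. One GPS fix is emitted on the first sample, displaced from the
#' true origin by the seeded GPS error.
#'
#' @param spec A [walk_spec()].
#' @param projection A [projection_spec()] used to place the true track.
#' @return List with `trace` (an NM [imu_trace()]) and `truth` (list:
#'   `segments` tibble with true `t_start`, `t_end`, `length`, `heading`;
#'   `track` tibble with the true N/E after each step; `origin_plane`,
#'   `gps_error_applied`).
#' @export
gen_walk_trace <- function(spec = walk_spec(), projection = projection_spec()) {
  stopifnot(inherits(spec, "walk_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  dt <- 0.01
  n_idle <- round(spec$idle_gap / dt)
  n_steps <- length(spec$step_lengths)

  v_y <- rep(0, n_idle)
  yaw_true <- rep(spec$headings[1], n_idle)
  seg_rows <- vector("list", n_steps)
  for (k in seq_len(n_steps)) {
    v_step <- step_velocity(spec$step_lengths[k], spec$speed,
                            spec$gait_amp, spec$gait_freq, dt)
    t_start <- length(v_y) * dt
    seg_rows[[k]] <- tibble(
      step = k,
      t_start = t_start,
      t_end = t_start + length(v_step) * dt,
      length = sum(v_step) * dt,  # exact integral of the constructed profile
      heading = spec$headings[k])
    v_y <- c(v_y, v_step)
    yaw_true <- c(yaw_true, rep(spec$headings[k], length(v_step)))
    v_y <- c(v_y, rep(0, n_idle))
    yaw_true <- c(yaw_true, rep(spec$headings[k], n_idle))
  }
  n <- length(v_y)
  tt <- (seq_len(n) - 1L) * dt
  a_true <- c(0, diff(v_y)) / dt  # rectangular-consistent: cumsum(a)*dt == v
  noise_sd <- spec$noise_idle / 3
  bias_bound <- if (spec$noise_idle > 0) 0.0098 else 0  # +-1 mg calibration bias
  bias <- stats::runif(1, -bias_bound, bias_bound)
  acc_y <- spec$accel_sensitivity * a_true + bias + stats::rnorm(n, 0, noise_sd)
  acc_x <- stats::rnorm(n, 0, noise_sd) + stats::runif(1, -bias_bound, bias_bound)
  # yaw is magnetic: geographic heading plus declination, light compass noise
  yaw_sd <- if (spec$noise_idle > 0) 1 else 0
  yaw <- wrap_degrees(yaw_true + spec$declination + stats::rnorm(n, 0, yaw_sd))

  truth_segments <- dplyr::bind_rows(seg_rows)
  # true track in the plane (geographic headings)
  delta <- displacement_to_plane(0, truth_segments$length, truth_segments$heading)
  origin_plane <- wgs84_to_plane(spec$origin[["lat"]], spec$origin[["lon"]],
                                 projection)
  track <- tibble(step = c(0L, truth_segments$step),
                  N = origin_plane$N + c(0, cumsum(delta$dN)),
                  E = origin_plane$E + c(0, cumsum(delta$dE)))

  err_mag <- stats::runif(1, 0, spec$gps_error)
  err_dir <- stats::runif(1, 0, 360)
  seed_plane <- tibble(N = origin_plane$N + err_mag * cos_deg(err_dir),
                       E = origin_plane$E + err_mag * sin_deg(err_dir))
  seed_geo <- plane_to_wgs84(seed_plane$N, seed_plane$E, projection)

  lat <- rep(NA_real_, n); lon <- rep(NA_real_, n)
  lat[1] <- seed_geo$lat; lon[1] <- seed_geo$lon
  trace <- imu_trace(
    tibble(t = tt, acc_x = acc_x, acc_y = acc_y, yaw = yaw,
           lat = lat, lon = lon),
    dt = dt, mode = "NM", label = sprintf("synthetic-walk-seed%d", spec$seed))
  list(trace = trace,
       truth = list(segments = truth_segments, track = track,
                    origin_plane = origin_plane,
                    gps_error_applied = err_mag))
}

#' Branch-scan specification
#'
#' One acquisition-control recording: idle lead-in while the operator
#' focuses the branch, a scan of fixed duration at one of the three speed
#' classes, and a trailing idle before the recording stops. During the scan
#' the gyroscope Y channel carries white hand-tremor angular velocity well
#' above the idle noise floor.
#'
#' @param duration Scan duration, seconds (default 15, the published average
#'   for a 50 cm branch at ~3 cm/s).
#' @param speed_class `"low"`, `"medium"` or `"high"`; sets the nominal scan
#'   speed (3, 7.5, 12.5 cm/s) recorded in the ground truth.
#' @param t_on Idle lead-in before movement starts, seconds.
#' @param t_tail Trailing idle after the scan, seconds.
#' @param gyro_move Tremor angular-velocity sd during the scan, rad/s.
#' @param gyro_noise Idle gyroscope noise sd, rad/s.
#' @param seed Integer seed.
#' @return A `scan_spec` list.
#' @export
scan_spec <- function(duration = 15, speed_class = c("low", "medium", "high"),
                      t_on = 2, t_tail = 3, gyro_move = 0.15,
                      gyro_noise = 0.005, seed = 1L) {
  speed_class <- match.arg(speed_class)
  stopifnot(duration > 0, t_on >= 0, t_tail >= 0, gyro_move > 0)
  structure(list(duration = duration, speed_class = speed_class,
                 t_on = t_on, t_tail = t_tail, gyro_move = gyro_move,
                 gyro_noise = gyro_noise, seed = as.integer(seed)),
            class = "scan_spec")
}

#' Generate an acquisition-control branch-scan trace
#'
#' @param spec A [scan_spec()].
#' @return List with `trace` (an ACM [imu_trace()]) and `truth` (list:
#'   `t_start`, `t_end`, `mean_speed` cm/s, `speed_class`).
#' @export
gen_scan_trace <- function(spec = scan_spec()) {
  stopifnot(inherits(spec, "scan_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  dt <- 0.01
  n_on <- round(spec$t_on / dt)
  n_mv <- round(spec$duration / dt)
  n_tail <- round(spec$t_tail / dt)
  n <- n_on + n_mv + n_tail
  gyro_y <- stats::rnorm(n, 0, spec$gyro_noise)
  moving_idx <- n_on + seq_len(n_mv)
  gyro_y[moving_idx] <- stats::rnorm(n_mv, 0, spec$gyro_move)
  mean_speed <- switch(spec$speed_class, low = 3, medium = 7.5, high = 12.5)
  trace <- imu_trace(
    tibble(t = (seq_len(n) - 1L) * dt, gyro_y = gyro_y),
    dt = dt, mode = "ACM",
    label = sprintf("synthetic-scan-%s-seed%d", spec$speed_class, spec$seed))
  list(trace = trace,
       truth = list(t_start = spec$t_on, t_end = spec$t_on + spec$duration,
                    mean_speed = mean_speed, speed_class = spec$speed_class))
}

# Separable convolution with replicate padding (rows then columns).
sep_convolve <- function(img, k) {
  r <- (length(k) - 1L) / 2
  h <- nrow(img); w <- ncol(img)
  clamp <- function(i, n) pmin(pmax(i, 1L), n)
  out <- matrix(0, h, w)
  for (j in seq_along(k)) {   # along columns (x)
    out <- out + k[j] * img[, clamp(seq_len(w) + j - 1L - r, w), drop = FALSE]
  }
  out2 <- matrix(0, h, w)
  for (j in seq_along(k)) {   # along rows (y)
    out2 <- out2 + k[j] * out[clamp(seq_len(h) + j - 1L - r, h), , drop = FALSE]
  }
  out2
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Horizontal box blur of length `len` pixels (motion blur).
motion_blur <- function(img, len) {
  if (len <= 1) return(img)
  k <- rep(1 / len, len)
  if (length(k) %% 2 == 0) k <- c(k, 0)  # pad to odd length
  r <- (length(k) - 1L) / 2
  h <- nrow(img); w <- ncol(img)
  clamp <- function(i, n) pmin(pmax(i, 1L), n)
  out <- matrix(0, h, w)
  for (j in seq_along(k)) {
    if (k[j] != 0) out <- out + k[j] * img[, clamp(seq_len(w) + j - 1L - r, w), drop = FALSE]
  }
  out
}

#' Generate a synthetic branch-like image
#'
#' Renders a red-dominant scene loosely resembling a fruit-bearing branch
#' viewed from above: a textured background band, a horizontal branch,
#' red-dominant ellipses (fruit) and green blobs (leaves) spread across the
#' central band so that all three default ROIs contain structure. Optional
#' Gaussian blur emulates defocus; optional horizontal box blur emulates
#' motion blur at medium/high scan speed. This is a synthetic stand-in for
#' field footage, not a photorealistic rendering.
#'
#' @param seed Integer seed.
#' @param blur_sigma Gaussian defocus sd, pixels (0 = sharp).
#' @param motion_blur_len Horizontal motion-blur length, pixels (0 = none).
#' @param width,height Image size (default Full-HD 1920 x 1080).
#' @return List with `image` (h x w x 3 array, 0..255) and `truth` (list
#'   with `blur_sigma`, `motion_blur_len`).
#' @export
gen_branch_image <- function(seed = 7L, blur_sigma = 0, motion_blur_len = 0,
                             width = 1920, height = 1080) {
  stopifnot(blur_sigma >= 0, motion_blur_len >= 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  h <- height; w <- width
  xs <- matrix(seq_len(w), h, w, byrow = TRUE)
  ys <- matrix(seq_len(h), h, w)

  # dim cluttered background with per-pixel speckle texture
  r_ch <- matrix(60, h, w) + matrix(stats::rnorm(h * w, 0, 35), h, w)
  g_ch <- matrix(70, h, w) + matrix(stats::rnorm(h * w, 0, 35), h, w)
  b_ch <- matrix(45, h, w) + matrix(stats::rnorm(h * w, 0, 20), h, w)

  # horizontal branch through the central band
  branch <- abs(ys - h / 2 - 8 * sinpi(2 * xs / w)) < h / 45
  r_ch[branch] <- 95 + stats::rnorm(sum(branch), 0, 35)
  g_ch[branch] <- 70 + stats::rnorm(sum(branch), 0, 28)
  b_ch[branch] <- 40 + stats::rnorm(sum(branch), 0, 18)

  # fruit: red-dominant ellipses clustered on the central band
  n_fruit <- 60
  fx <- stats::runif(n_fruit, 0.03 * w, 0.97 * w)
  fy <- h / 2 + stats::rnorm(n_fruit, 0, h / 18)
  fr <- stats::runif(n_fruit, 12, 26)
  for (i in seq_len(n_fruit)) {
    d2 <- ((xs - fx[i]) / fr[i])^2 + ((ys - fy[i]) / (0.85 * fr[i]))^2
    inside <- d2 < 1
    shade <- pmax(0, 1 - d2[inside])  # simple radial shading
    r_ch[inside] <- 140 + 90 * shade + stats::rnorm(sum(inside), 0, 28)
    g_ch[inside] <- 35 + 35 * shade + stats::rnorm(sum(inside), 0, 20)
    b_ch[inside] <- 30 + 20 * shade + stats::rnorm(sum(inside), 0, 15)
  }
  # leaves: green blobs, some overlapping the band
  n_leaf <- 25
  lx <- stats::runif(n_leaf, 0.03 * w, 0.97 * w)
  ly <- h / 2 + stats::rnorm(n_leaf, 0, h / 6)
  lr <- stats::runif(n_leaf, 25, 60)
  for (i in seq_len(n_leaf)) {
    d2 <- ((xs - lx[i]) / (1.6 * lr[i]))^2 + ((ys - ly[i]) / lr[i])^2
    inside <- d2 < 1
    shade <- pmax(0, 1 - d2[inside])
    r_ch[inside] <- 40 + 30 * shade + stats::rnorm(sum(inside), 0, 18)
    g_ch[inside] <- 110 + 70 * shade + stats::rnorm(sum(inside), 0, 26)
    b_ch[inside] <- 35 + 20 * shade + stats::rnorm(sum(inside), 0, 14)
  }

  chans <- list(r_ch, g_ch, b_ch)
  if (blur_sigma > 0) {
    k <- gaussian_kernel(blur_sigma)
    chans <- purrr::map(chans, sep_convolve, k = k)
  }
  if (motion_blur_len > 1) {
    chans <- purrr::map(chans, motion_blur, len = motion_blur_len)
  }
  img <- array(0, dim = c(h, w, 3))
  for (i in 1:3) img[, , i] <- pmin(255, pmax(0, chans[[i]]))
  list(image = img,
       truth = list(blur_sigma = blur_sigma, motion_blur_len = motion_blur_len))
}

#' Write a frame to PNG
#'
#' @param img Matrix or RGB array on the 0..255 scale.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frame_png <- function(img, path) {
  png::writePNG(img / 255, path)
  invisible(path)
}

# Save/restore the global RNG state so generators are pure.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
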