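# Degree trigonometry and circular helpers shared across modules.

deg2rad <- function(x) x * pi / 180

cos_deg <- function(x) cospi(x / 180)

sin_deg <- function(x) sinpi(x / 180)

#' Wrap an angle in degrees to [0, 360)
#'
#' @param x Numeric vector of angles in degrees.
#' @return Numeric vector in `[0, 360)`.
#' @examples
#' wrap_degrees(c(-6.13, 364.13, 360))
#' @export
wrap_degrees <- function(x) {
  out <- x %% 360
  out[out == 360] <- 0
  out
}

#' Circular mean of angles in degrees
#'
#' Mean direction of a set of compass angles, computed on the unit circle so
#' that e.g. 359 and 1 average to 0, not 180.
#'
#' @param x Numeric vector of angles, degrees.
#' @return Mean direction in `[0, 360)`.
#' @examples
#' circular_mean(c(359, 1))
#' @export
circular_mean <- function(x) {
  stopifnot(length(x) >= 1)
  wrap_degrees(atan2(mean(sin_deg(x)), mean(cos_deg(x))) * 180 / pi)
}

# Wrap to (-180, 180] (pitch/roll convention).
wrap_degrees_sym <- function(x) {
  out <- -((-x + 180) %% 360) + 180
  out[out == -180] <- 180
  out
}

# Interpolate angles along the shortest arc. `t_out` must lie within range(t).
# `wrap` selects the output convention: [0, 360) for yaw, (-180, 180] for
# pitch/roll.
interp_circular <- function(t, theta, t_out, wrap = c("pos", "sym")) {
  wrap <- match.arg(wrap)
  rewrap <- if (wrap == "pos") wrap_degrees else wrap_degrees_sym
  if (length(t) == 1) return(rep(rewrap(theta), length(t_out)))
  # unwrap: accumulate jumps so consecutive differences are in (-180, 180]
  d <- diff(theta)
  d <- ((d + 180) %% 360) - 180
  unwrapped <- theta[1] + c(0, cumsum(d))
  rewrap(stats::approx(t, unwrapped, xout = t_out, rule = 2)$y)
}
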