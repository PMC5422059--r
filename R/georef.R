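# Georeferencing: WGS84 <-> Gauss-Kruger plane coordinates, magnetic
# declination correction, rotation of device-frame displacements into the
# plane frame, and accumulation of the track from a single GPS seed.
#
# The transverse-Mercator forward/inverse is the classical series expansion
# (meridian arc + footpoint latitude) at scale factor 1, which closes round
# trips well below a millimetre for the few degrees of longitude offset a
# survey zone spans. No projection library ships with this toolchain, so the
# projection is implemented here and exercised against a geodesic-distance
# oracle in the tests.

#' Gauss-Kruger projection specification
#'
#' Defaults to the Colombian MAGNA-SIRGAS Bogota zone (GRS80 ellipsoid,
#' origin 4d35'46.3215" N, 74d04'39.0285" W, false northing and easting
#' 1,000,000 m), the national frame in use where coffee parcels in the
#' central mountain range are surveyed. All parameters are configurable per
#' site.
#'
#' @param a Semi-major axis, metres.
#' @param f Ellipsoid flattening (in (0, 1/290)).
#' @param lon0 Central meridian, degrees.
#' @param lat0 Latitude of origin, degrees.
#' @param false_northing,false_easting Metres.
#' @return A `projection_spec` list.
#' @export
projection_spec <- function(a = 6378137, f = 1 / 298.257222101,
                            lon0 = -(74 + 4 / 60 + 39.0285 / 3600),
                            lat0 = 4 + 35 / 60 + 46.3215 / 3600,
                            false_northing = 1000000,
                            false_easting = 1000000) {
  if (!is.finite(a) || a <= 0) abort("`a` must be positive and finite.")
  if (!is.finite(f) || f <= 0 || f >= 1 / 290) abort("`f` must lie in (0, 1/290).")
  stopifnot(is.finite(lon0), is.finite(lat0),
            is.finite(false_northing), is.finite(false_easting))
  structure(list(a = a, f = f, lon0 = lon0, lat0 = lat0,
                 false_northing = false_northing,
                 false_easting = false_easting),
            class = "projection_spec")
}

# Meridian arc length from the equator (Snyder 3-21).
meridian_arc <- function(phi, a, e2) {
  a * ((1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256) * phi -
       (3 * e2 / 8 + 3 * e2^2 / 32 + 45 * e2^3 / 1024) * sin(2 * phi) +
       (15 * e2^2 / 256 + 45 * e2^3 / 1024) * sin(4 * phi) -
       (35 * e2^3 / 3072) * sin(6 * phi))
}

#' Project WGS84 coordinates to the Gauss-Kruger plane
#'
#' Transverse-Mercator forward projection at scale factor 1.
#'
#' @param lat,lon Degrees (vectors of equal length); `abs(lat)` must be
#'   strictly below 90.
#' @param spec A [projection_spec()].
#' @return Tibble with columns `N` and `E` (metres).
#' @export
wgs84_to_plane <- function(lat, lon, spec = projection_spec()) {
  stopifnot(inherits(spec, "projection_spec"))
  if (any(abs(lat) >= 90)) abort("Latitude must lie strictly between -90 and 90.")
  e2 <- spec$f * (2 - spec$f)
  ep2 <- e2 / (1 - e2)
  phi <- deg2rad(lat)
  dlam <- deg2rad(lon - spec$lon0)
  sphi <- sin(phi); cphi <- cos(phi); tphi <- tan(phi)
  Nu <- spec$a / sqrt(1 - e2 * sphi^2)
  Tt <- tphi^2
  Cc <- ep2 * cphi^2
  A <- dlam * cphi
  M <- meridian_arc(phi, spec$a, e2)
  M0 <- meridian_arc(deg2rad(spec$lat0), spec$a, e2)
  x <- Nu * (A + (1 - Tt + Cc) * A^3 / 6 +
             (5 - 18 * Tt + Tt^2 + 72 * Cc - 58 * ep2) * A^5 / 120)
  y <- M - M0 + Nu * tphi * (A^2 / 2 + (5 - Tt + 9 * Cc + 4 * Cc^2) * A^4 / 24 +
             (61 - 58 * Tt + Tt^2 + 600 * Cc - 330 * ep2) * A^6 / 720)
  tibble(N = spec$false_northing + y, E = spec$false_easting + x)
}

#' Inverse Gauss-Kruger projection back to WGS84
#'
#' @param N,E Plane coordinates, metres (vectors of equal length).
#' @param spec A [projection_spec()].
#' @return Tibble with columns `lat` and `lon` (degrees).
#' @export
plane_to_wgs84 <- function(N, E, spec = projection_spec()) {
  stopifnot(inherits(spec, "projection_spec"))
  e2 <- spec$f * (2 - spec$f)
  ep2 <- e2 / (1 - e2)
  e1 <- (1 - sqrt(1 - e2)) / (1 + sqrt(1 - e2))
  M0 <- meridian_arc(deg2rad(spec$lat0), spec$a, e2)
  M <- M0 + (N - spec$false_northing)
  mu <- M / (spec$a * (1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256))
  # footpoint latitude (Snyder 3-26)
  phi1 <- mu + (3 * e1 / 2 - 27 * e1^3 / 32) * sin(2 * mu) +
    (21 * e1^2 / 16 - 55 * e1^4 / 32) * sin(4 * mu) +
    (151 * e1^3 / 96) * sin(6 * mu) +
    (1097 * e1^4 / 512) * sin(8 * mu)
  sphi <- sin(phi1); cphi <- cos(phi1); tphi <- tan(phi1)
  C1 <- ep2 * cphi^2
  T1 <- tphi^2
  N1 <- spec$a / sqrt(1 - e2 * sphi^2)
  R1 <- spec$a * (1 - e2) / (1 - e2 * sphi^2)^1.5
  D <- (E - spec$false_easting) / N1
  phi <- phi1 - (N1 * tphi / R1) *
    (D^2 / 2 - (5 + 3 * T1 + 10 * C1 - 4 * C1^2 - 9 * ep2) * D^4 / 24 +
     (61 + 90 * T1 + 298 * C1 + 45 * T1^2 - 252 * ep2 - 3 * C1^2) * D^6 / 720)
  lam <- deg2rad(spec$lon0) +
    (D - (1 + 2 * T1 + C1) * D^3 / 6 +
     (5 - 2 * C1 + 28 * T1 - 3 * C1^2 + 8 * ep2 + 24 * T1^2) * D^5 / 120) / cphi
  tibble(lat = phi * 180 / pi, lon = lam * 180 / pi)
}

#' Correct a magnetic azimuth to geographic heading
#'
#' The handset reports yaw against magnetic north; plane coordinates are
#' aligned with geographic north, so the site's magnetic declination is
#' subtracted (published site value -6.13 degrees).
#'
#' @param azimuth Degrees clockwise from magnetic north, in `[0, 360)`.
#' @param declination Site magnetic declination, degrees.
#' @return Geographic heading theta in `[0, 360)`.
#' @examples
#' heading_correction(100, -6.13)
#' @export
heading_correction <- function(azimuth, declination = -6.13) {
  if (any(azimuth < 0 | azimuth >= 360)) abort("`azimuth` must lie in [0, 360).")
  wrap_degrees(azimuth - declination)
}

#' Rotate a device-frame displacement into the plane frame
#'
#' The device Y axis points along the heading theta and X across it, so the
#' northing/easting increments are
#' `dN = dY * cos(theta) + dX * cos(theta + 90)` and
#' `dE = dY * sin(theta) + dX * sin(theta + 90)`, with trigonometry in
#' degrees.
#'
#' @param dX,dY Device-frame displacements, metres.
#' @param theta Geographic heading, degrees.
#' @return Tibble with `dN`, `dE` (metres).
#' @examples
#' displacement_to_plane(0, 1, 0)     # one metre due north
#' displacement_to_plane(0, 0.5, 6.13)
#' @export
displacement_to_plane <- function(dX, dY, theta) {
  stopifnot(all(is.finite(theta)))
  tibble(dN = dY * cos_deg(theta) + dX * cos_deg(theta + 90),
         dE = dY * sin_deg(theta) + dX * sin_deg(theta + 90))
}

#' Accumulate a georeferenced track from a GPS seed
#'
#' The first track point is the GPS seed converted to plane coordinates;
#' every following point is dead-reckoned by rotating each movement's
#' calibrated device-frame displacement into the plane frame with its
#' declination-corrected heading and adding it to the running position.
#' Every point carries both plane and ellipsoidal coordinates.
#'
#' @param seed List or one-row data frame with `lat`, `lon` (WGS84 degrees).
#' @param movements Data frame with one row per movement segment: columns
#'   `dX`, `dY` (metres, device frame) and `azimuth` (mean magnetic heading,
#'   degrees). May have zero rows.
#' @param spec A [projection_spec()].
#' @param declination Site magnetic declination, degrees.
#' @return An `ins_track` tibble: `segment_id` (0 for the seed), `N`, `E`,
#'   `lat`, `lon`, `source` (`"GPS"` for the seed, `"INS"` after), `theta`.
#' @export
accumulate_track <- function(seed, movements = NULL, spec = projection_spec(),
                             declination = -6.13) {
  if (is.null(seed) || is.null(seed$lat) || is.null(seed$lon) ||
      is.na(seed$lat[1]) || is.na(seed$lon[1])) {
    abort(paste("No GPS fix to seed the track; record a fix in the log or",
                "pass a manual seed (lat/lon)."))
  }
  p0 <- wgs84_to_plane(seed$lat[1], seed$lon[1], spec)
  if (is.null(movements)) movements <- tibble(dX = double(0), dY = double(0),
                                              azimuth = double(0))
  movements <- as_tibble(movements)
  theta <- if (nrow(movements)) heading_correction(movements$azimuth, declination) else double(0)
  delta <- displacement_to_plane(movements$dX, movements$dY, theta)
  track <- tibble(
    segment_id = c(0L, seq_len(nrow(movements))),
    N = p0$N + c(0, cumsum(delta$dN)),
    E = p0$E + c(0, cumsum(delta$dE)),
    source = c("GPS", rep("INS", nrow(movements))),
    theta = c(NA_real_, theta))
  geo <- plane_to_wgs84(track$N, track$E, spec)
  track$lat <- geo$lat
  track$lon <- geo$lon
  track <- track[, c("segment_id", "N", "E", "lat", "lon", "source", "theta")]
  structure(track, class = c("ins_track", class(tibble())), spec = spec,
            declination = declination)
}

#' Plot a georeferenced track
#'
#' @param object An `ins_track`.
#' @param ... Unused.
#' @return A ggplot of the track in plane coordinates (E on x, N on y, equal
#'   scales), GPS seed marked.
#' @export
autoplot.ins_track <- function(object, ...) {
  df <- as_tibble(as.data.frame(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$E, y = .data$N)) +
    ggplot2::geom_path(colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$source), size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "East [m]", y = "North [m]", colour = NULL,
                  title = "GPS-seeded inertial track")
}

#' Write a track as GeoJSON
#'
#' Emits a FeatureCollection with one LineString for the path and one Point
#' per track position (properties: segment_id, source, theta).
#'
#' @param track An `ins_track`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_track_geojson <- function(track, path) {
  coords <- purrr::map(seq_len(nrow(track)),
                       function(i) c(track$lon[i], track$lat[i]))
  points <- purrr::map(seq_len(nrow(track)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point", coordinates = coords[[i]]),
         properties = list(segment_id = track$segment_id[i],
                           source = track$source[i],
                           theta = track$theta[i]))
  })
  line <- list(type = "Feature",
               geometry = list(type = "LineString", coordinates = coords),
               properties = list(name = "ins_track"))
  fc <- list(type = "FeatureCollection", features = c(list(line), points))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}
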