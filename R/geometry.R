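# Spherical geometry: an azimuthal-equidistant projection about a local
# origin. Distances from the origin are exact great-circle distances, which
# is what the gyradius needs; all planar analysis happens in meters.

#' Mean Earth radius used for all spherical geometry, in meters
#' @export
EARTH_RADIUS_M <- 6371000

#' Project coordinates to a local planar frame
#'
#' Azimuthal-equidistant projection on a sphere of radius
#' [EARTH_RADIUS_M] about `origin`. The planar distance of any point from
#' the origin equals its great-circle distance, so radial statistics
#' (distance from expected location, gyradius) are exact.
#'
#' @param lat,lon Numeric vectors of WGS84 decimal degrees.
#' @param origin Length-2 numeric `c(lat, lon)` of the projection origin.
#' @return A list with numeric vectors `x` (meters east), `y` (meters
#'   north) and the `origin`, of class `gh_planar`.
#' @export
project_local <- function(lat, lon, origin) {
  abort_if(length(origin) != 2 || any(!is.finite(origin)),
           "projection origin must be finite c(lat, lon)")
  phi0 <- origin[1] * pi / 180
  lam0 <- origin[2] * pi / 180
  phi <- lat * pi / 180
  dlam <- (lon * pi / 180) - lam0
  cosc <- sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(dlam)
  cosc <- pmin(1, pmax(-1, cosc))
  c_ang <- acos(cosc)
  abort_if(any(c_ang > pi - 1e-6),
           "point(s) antipodal to the projection origin are outside the projection's extent")
  # k = c / sin(c), -> 1 as c -> 0
  k <- ifelse(c_ang < 1e-12, 1, c_ang / sin(c_ang))
  x <- EARTH_RADIUS_M * k * cos(phi) * sin(dlam)
  y <- EARTH_RADIUS_M * k *
    (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(dlam))
  structure(list(x = x, y = y, origin = as.numeric(origin)),
            class = "gh_planar")
}

#' Invert the local planar projection
#'
#' @param x,y Meters east/north in the frame produced by [project_local()].
#' @param origin The projection origin used for the forward projection.
#' @return A list with numeric vectors `lat` and `lon` in degrees.
#' @export
unproject_local <- function(x, y, origin) {
  phi0 <- origin[1] * pi / 180
  lam0 <- origin[2] * pi / 180
  rho <- sqrt(x^2 + y^2)
  c_ang <- rho / EARTH_RADIUS_M
  sinc <- sin(c_ang)
  cosc <- cos(c_ang)
  safe_rho <- ifelse(rho < 1e-12, 1, rho)
  phi <- asin(pmin(1, pmax(-1, cosc * sin(phi0) + (y / safe_rho) * sinc * cos(phi0))))
  lam <- lam0 + atan2(x * sinc,
                      safe_rho * cos(phi0) * cosc - y * sin(phi0) * sinc)
  phi <- ifelse(rho < 1e-12, phi0, phi)
  lam <- ifelse(rho < 1e-12, lam0, lam)
  list(lat = phi * 180 / pi,
       lon = ((lam * 180 / pi + 180) %% 360) - 180)
}

#' Great-circle distance between point pairs
#'
#' Haversine distance on the [EARTH_RADIUS_M] sphere, vectorized over pairs.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Distances in meters.
#' @export
great_circle_m <- function(lat1, lon1, lat2, lon2) {
  p1 <- lat1 * pi / 180
  p2 <- lat2 * pi / 180
  dphi <- (lat2 - lat1) * pi / 180
  dlam <- (lon2 - lon1) * pi / 180
  a <- sin(dphi / 2)^2 + cos(p1) * cos(p2) * sin(dlam / 2)^2
  2 * EARTH_RADIUS_M * asin(pmin(1, sqrt(a)))
}
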