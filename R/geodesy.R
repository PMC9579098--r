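# Shore-station geodesy: theodolite angles <-> positions with earth-curvature
# and atmospheric-refraction corrections, on a local planar grid anchored at
# the station.

# Mean earth radius (m); one constant shared by every conversion so that
# forward/inverse transforms round-trip exactly.
.EARTH_RADIUS_M <- 6371008.8
.KM_PER_DEG <- pi * (.EARTH_RADIUS_M / 1000) / 180

#' Define a shore observation station
#'
#' A station is a surveyed point of known geographic position and instrument
#' height above mean sea level. All local planar coordinates produced by the
#' package are kilometres east (`x`) and north (`y`) of the station anchor.
#'
#' @param id Station identifier (character or integer).
#' @param lat,lon Geographic position of the theodolite (WGS84 decimal
#'   degrees).
#' @param height_m Instrument height above mean sea level in metres; must be
#'   positive. Coastal towers in shallow-shelf whale studies typically range
#'   from roughly 10 to 25 m.
#' @param ref_azimuth_deg Azimuth (degrees clockwise from true north) of the
#'   horizontal-circle zero of the theodolite.
#' @param max_range_km Maximum reliable tracking range; fixes beyond this are
#'   suppressed by the observation simulator. Practical limits scale with
#'   height: roughly 6 km for 10-m stations up to 12 km for 20-m-plus
#'   stations.
#' @return An object of class `brs_station`.
#' @export
brs_station <- function(id, lat, lon, height_m, ref_azimuth_deg = 0,
                        max_range_km = 12) {
  stopifnot(is.numeric(height_m), length(height_m) == 1L)
  if (height_m <= 0) stop("station height must be > 0 m")
  if (ref_azimuth_deg < 0 || ref_azimuth_deg >= 360)
    stop("reference azimuth must lie in [0, 360)")
  structure(list(id = id, lat = lat, lon = lon, height_m = height_m,
                 ref_azimuth_deg = ref_azimuth_deg,
                 max_range_km = max_range_km),
            class = "brs_station")
}

#' @export
print.brs_station <- function(x, ...) {
  cat(sprintf("Shore station '%s' at (%.5f, %.5f), height %.1f m, max range %.1f km\n",
              as.character(x$id), x$lat, x$lon, x$height_m, x$max_range_km))
  invisible(x)
}

# Local planar grid: equirectangular plane anchored at (lat0, lon0).
# Adequate below ~50 km extent where planar error is far below theodolite
# measurement error.
local_xy <- function(lat, lon, lat0, lon0) {
  list(x = (lon - lon0) * .KM_PER_DEG * cos(lat0 * pi / 180),
       y = (lat - lat0) * .KM_PER_DEG)
}

local_lonlat <- function(x, y, lat0, lon0) {
  list(lat = lat0 + y / .KM_PER_DEG,
       lon = lon0 + x / (.KM_PER_DEG * cos(lat0 * pi / 180)))
}

# Effective earth radius under the standard surveying refraction model:
# rays bend with curvature k times the earth's, equivalent to sighting over
# a sphere of radius R / (1 - k).
effective_radius_m <- function(refraction_k = 0.13) {
  .EARTH_RADIUS_M / (1 - refraction_k)
}

#' Convert a theodolite declination to ground range
#'
#' Exact spherical solution for the ground (arc) distance to a sea-surface
#' target seen at depression angle `theta` below the true horizontal from an
#' instrument `h` metres above the surface, over an effective earth radius
#' that absorbs atmospheric refraction. In the flat-earth limit the familiar
#' `h / tan(theta)` is recovered.
#'
#' @param theta_deg Depression angle below the true horizontal (degrees),
#'   strictly between the horizon dip angle and 90.
#' @param height_m Effective instrument height above the water (m): station
#'   height minus tide height.
#' @param refraction_k Refraction coefficient (dimensionless, default 0.13,
#'   standard terrestrial value).
#' @return Ground range in metres.
#' @export
declination_to_range <- function(theta_deg, height_m, refraction_k = 0.13) {
  if (any(height_m <= 0)) stop("effective height must be > 0 (tide above instrument?)")
  re <- effective_radius_m(refraction_k)
  theta <- theta_deg * pi / 180
  if (any(theta_deg >= 90) || any(theta_deg <= 0))
    stop("vertical (depression) angle must lie in (0, 90) degrees")
  # sine rule in the (earth centre, observer, target) triangle; the visible
  # intersection has an obtuse angle at the target.
  s <- (re + height_m) * cos(theta) / re
  dip <- acos(re / (re + height_m))
  if (any(s > 1))
    stop(sprintf("angle at or beyond the horizon (dip = %.4f deg): target not on the sea surface",
                 dip[which(s > 1)[1]] * 180 / pi))
  phi <- theta + asin(s) - pi / 2
  re * phi
}

#' Convert ground range to a theodolite declination
#'
#' Exact inverse of [declination_to_range()].
#'
#' @param range_m Ground (arc) range in metres, > 0.
#' @inheritParams declination_to_range
#' @return Depression angle below the true horizontal, degrees.
#' @export
range_to_declination <- function(range_m, height_m, refraction_k = 0.13) {
  if (any(range_m <= 0)) stop("range must be > 0")
  if (any(height_m <= 0)) stop("effective height must be > 0")
  re <- effective_radius_m(refraction_k)
  phi <- range_m / re
  atan2((re + height_m) - re * cos(phi), re * sin(phi)) * 180 / pi
}

#' Convert a theodolite fix to a geographic position
#'
#' Solves the curvature-and-refraction-corrected declination equation for
#' ground range and composes it with the horizontal angle (relative to the
#' station's reference azimuth) on the station's local planar grid.
#'
#' @param vertical_deg Depression angle(s) below the true horizontal, degrees.
#' @param horizontal_deg Horizontal circle reading(s), degrees; true azimuth
#'   is `ref_azimuth_deg + horizontal_deg` (mod 360).
#' @param station A [brs_station()].
#' @param tide_m Tide height above mean sea level (m); reduces the effective
#'   instrument height.
#' @param refraction_k Refraction coefficient, default 0.13.
#' @return A data.frame with columns `x`, `y` (km east/north of the station),
#'   `lat`, `lon`, `range_km`, `azimuth_deg`.
#' @export
fix_to_position <- function(vertical_deg, horizontal_deg, station, tide_m = 0,
                            refraction_k = 0.13) {
  h <- station$height_m - tide_m
  r_km <- declination_to_range(vertical_deg, h, refraction_k) / 1000
  az <- (station$ref_azimuth_deg + horizontal_deg) %% 360
  azr <- az * pi / 180
  x <- r_km * sin(azr)
  y <- r_km * cos(azr)
  ll <- local_lonlat(x, y, station$lat, station$lon)
  data.frame(x = x, y = y, lat = ll$lat, lon = ll$lon,
             range_km = r_km, azimuth_deg = az)
}

#' Convert a position to theodolite angles
#'
#' Exact inverse of [fix_to_position()] under identical curvature/refraction
#' corrections. Positions may be given either as local planar `x`/`y` (km) or
#' as `lat`/`lon`.
#'
#' @param x,y Local planar coordinates (km east/north of the station), or
#'   `NULL` if `lat`/`lon` are given.
#' @param lat,lon Geographic coordinates (decimal degrees), used when `x` is
#'   `NULL`.
#' @inheritParams fix_to_position
#' @return A data.frame with columns `vertical_deg`, `horizontal_deg`,
#'   `range_km`, `azimuth_deg`.
#' @export
position_to_angles <- function(station, x = NULL, y = NULL,
                               lat = NULL, lon = NULL, tide_m = 0,
                               refraction_k = 0.13) {
  if (is.null(x)) {
    xy <- local_xy(lat, lon, station$lat, station$lon)
    x <- xy$x; y <- xy$y
  }
  r_km <- sqrt(x^2 + y^2)
  if (any(r_km == 0)) stop("position coincides with the station")
  h <- station$height_m - tide_m
  vert <- range_to_declination(r_km * 1000, h, refraction_k)
  az <- (atan2(x, y) * 180 / pi) %% 360
  data.frame(vertical_deg = vert,
             horizontal_deg = (az - station$ref_azimuth_deg) %% 360,
             range_km = r_km, azimuth_deg = az)
}

#' Minimum distance from a point to a shoreline polyline
#'
#' Locally planar point-to-segment minimum over all polyline segments.
#'
#' @param x,y Point coordinates (km, station-local plane). Vectors accepted.
#' @param shoreline A data.frame (or matrix) with columns `x`, `y` giving the
#'   polyline vertices in the same coordinate system, in order.
#' @return Distance(s) in km, >= 0.
#' @export
distance_from_shore <- function(x, y, shoreline) {
  shoreline <- as.data.frame(shoreline)
  if (nrow(shoreline) < 1L) stop("empty shoreline polyline")
  sx <- shoreline$x; sy <- shoreline$y
  n <- length(sx)
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    if (n == 1L) { out[i] <- sqrt((x[i] - sx)^2 + (y[i] - sy)^2); next }
    ax <- sx[-n]; ay <- sy[-n]; bx <- sx[-1]; by <- sy[-1]
    dx <- bx - ax; dy <- by - ay
    len2 <- dx^2 + dy^2
    t <- ifelse(len2 == 0, 0, pmin(1, pmax(0, ((x[i] - ax) * dx + (y[i] - ay) * dy) / len2)))
    px <- ax + t * dx; py <- ay + t * dy
    out[i] <- sqrt(min((x[i] - px)^2 + (y[i] - py)^2))
  }
  out
}
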