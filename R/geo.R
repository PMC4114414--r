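#' Mean Earth radius in kilometers
#'
#' The IUGG mean Earth radius, used as the default sphere radius for all
#' great-circle distance computations. All distances in this package are
#' spherical; geodesic (ellipsoidal) precision is out of scope because the
#' analysis operates at a 500 m home-radius resolution.
#'
#' @format A length-one numeric, kilometers.
#' @export
EARTH_RADIUS_KM <- 6371.0088

#' Construct a validated geographic point
#'
#' A WGS84 coordinate pair in decimal degrees. Latitude must lie in
#' \[-90, 90\] and longitude in \[-180, 180\]; violations raise an error
#' naming the offending field.
#'
#' @param lat Latitude, decimal degrees.
#' @param lon Longitude, decimal degrees.
#' @return A named numeric vector `c(lat, lon)` of class `"geo_point"`.
#' @examples
#' home <- geo_point(40.0, -70.0)
#' @export
geo_point <- function(lat, lon) {
  validate_coords(lat, lon)
  structure(c(lat = as.numeric(lat), lon = as.numeric(lon)),
            class = "geo_point")
}

#' @export
print.geo_point <- function(x, ...) {
  cat(sprintf("<geo_point> lat %.6f, lon %.6f\n", x[["lat"]], x[["lon"]]))
  invisible(x)
}

validate_coords <- function(lat, lon, call = rlang::caller_env()) {
  if (any(!is.finite(lat)) || any(lat < -90) || any(lat > 90)) {
    rlang::abort("`lat` must be finite and within [-90, 90] degrees.",
                 call = call)
  }
  if (any(!is.finite(lon)) || any(lon < -180) || any(lon > 180)) {
    rlang::abort("`lon` must be finite and within [-180, 180] degrees.",
                 call = call)
  }
  invisible(TRUE)
}

deg2rad <- function(x) x * pi / 180

#' Great-circle distance by the haversine formula
#'
#' Computes the spherical distance between coordinate pairs:
#' \deqn{d = 2R \arcsin\sqrt{\sin^2(\Delta\phi/2) +
#'   \cos\phi_1 \cos\phi_2 \sin^2(\Delta\lambda/2)}}
#' with angles in radians and \eqn{R} the sphere radius. Inputs and outputs
#' use decimal degrees and kilometers; conversion to radians is internal.
#' Vectorized over all coordinate arguments with the usual recycling.
#'
#' @param lat1,lon1 First point(s), decimal degrees.
#' @param lat2,lon2 Second point(s), decimal degrees.
#' @param radius_km Sphere radius in kilometers; default [EARTH_RADIUS_KM].
#' @return Distance(s) in kilometers; non-negative, symmetric in its
#'   arguments, and bounded by `pi * radius_km`.
#' @examples
#' haversine_km(0, 0, 0, 90)   # quarter of the equator, ~10007.6 km
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2, radius_km = EARTH_RADIUS_KM) {
  validate_coords(lat1, lon1)
  validate_coords(lat2, lon2)
  stopifnot(is.numeric(radius_km), length(radius_km) == 1L, radius_km > 0)
  phi1 <- deg2rad(lat1)
  phi2 <- deg2rad(lat2)
  dphi <- deg2rad(lat2 - lat1)
  dlam <- deg2rad(lon2 - lon1)
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  # clamp guards tiny negative / >1 excursions from floating-point rounding
  a <- pmin(pmax(a, 0), 1)
  2 * radius_km * asin(sqrt(a))
}

#' Distance from home for every fix in a trace
#'
#' @param trace A trace as returned by [ls_trace()].
#' @param home A [geo_point()] (or `c(lat, lon)`).
#' @param radius_km Sphere radius in kilometers.
#' @return A tibble with columns `time` and `distance_km`, one row per fix,
#'   in trace order. An empty trace yields an empty tibble.
#' @export
distance_from_home <- function(trace, home, radius_km = EARTH_RADIUS_KM) {
  home <- as_geo_point(home)
  tibble::tibble(
    time = trace$time,
    distance_km = haversine_km(trace$lat, trace$lon,
                               home[["lat"]], home[["lon"]],
                               radius_km = radius_km)
  )
}

as_geo_point <- function(x) {
  if (inherits(x, "geo_point")) return(x)
  if (is.numeric(x) && length(x) == 2L) {
    nm <- names(x)
    if (!is.null(nm) && all(c("lat", "lon") %in% nm)) {
      return(geo_point(x[["lat"]], x[["lon"]]))
    }
    return(geo_point(x[[1L]], x[[2L]]))
  }
  rlang::abort("`home` must be a geo_point or a numeric c(lat, lon).")
}
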