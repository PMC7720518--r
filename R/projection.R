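#' Equidistant conic projection
#'
#' Defines a spherical equidistant conic projection used to convert
#' longitude/latitude to planar coordinates in meters. The projection is
#' distance-true along meridians, which makes it a reasonable choice for
#' planar distance calculations over a study area spanning a degree or two
#' of latitude. Defaults place the standard parallels at 33 deg N and
#' 45 deg N with an origin in South Florida.
#'
#' @param lon0,lat0 Projection origin in decimal degrees.
#' @param lat1,lat2 Standard parallels in decimal degrees (`lat1 != lat2`).
#' @param radius Sphere radius in meters (mean Earth radius by default).
#' @return An object of class `eqc_projection`.
#' @examples
#' proj <- eqc_projection()
#' xy <- eqc_forward(proj, c(-80.2, -80.1), c(26.5, 26.6))
#' ll <- eqc_inverse(proj, xy$x, xy$y)
#' @export
eqc_projection <- function(lon0 = -80.25, lat0 = 26.5, lat1 = 33, lat2 = 45,
                           radius = 6371008.8) {
  stopifnot(lat1 != lat2, abs(lat1) < 90, abs(lat2) < 90)
  p1 <- lat1 * pi / 180
  p2 <- lat2 * pi / 180
  n <- (cos(p1) - cos(p2)) / (p2 - p1)
  G <- cos(p1) / n + p1
  structure(
    list(lon0 = lon0, lat0 = lat0, lat1 = lat1, lat2 = lat2,
         radius = radius, n = n, G = G,
         rho0 = radius * (G - lat0 * pi / 180)),
    class = "eqc_projection"
  )
}

#' @export
print.eqc_projection <- function(x, ...) {
  cat(sprintf(
    "Equidistant conic projection (parallels %g/%g, origin %g, %g)\n",
    x$lat1, x$lat2, x$lon0, x$lat0))
  invisible(x)
}

#' Forward / inverse equidistant conic transform
#'
#' `eqc_forward()` maps longitude/latitude (decimal degrees) to planar
#' x/y in meters; `eqc_inverse()` maps back. The two round-trip to well
#' under a meter.
#'
#' @param proj An [eqc_projection()] object.
#' @param lon,lat Coordinates in decimal degrees.
#' @param x,y Planar coordinates in meters.
#' @return A data.frame with columns `x`,`y` (forward) or `lon`,`lat`
#'   (inverse).
#' @export
eqc_forward <- function(proj, lon, lat) {
  stopifnot(inherits(proj, "eqc_projection"))
  if (any(!is.finite(lon)) || any(!is.finite(lat)))
    stop("non-finite coordinates passed to eqc_forward()")
  if (any(lat < -90 | lat > 90) || any(lon < -180 | lon > 180))
    stop("coordinates outside valid lon/lat ranges")
  phi <- lat * pi / 180
  lam <- (lon - proj$lon0) * pi / 180
  rho <- proj$radius * (proj$G - phi)
  # latitudes at/above the cone apex (G - phi <= 0) are outside validity
  if (any(proj$G - phi <= 0))
    stop("latitude outside the validity range of the projection")
  theta <- proj$n * lam
  data.frame(x = rho * sin(theta), y = proj$rho0 - rho * cos(theta))
}

#' @rdname eqc_forward
#' @export
eqc_inverse <- function(proj, x, y) {
  stopifnot(inherits(proj, "eqc_projection"))
  rho <- sign(proj$n) * sqrt(x^2 + (proj$rho0 - y)^2)
  theta <- atan2(x * sign(proj$n), (proj$rho0 - y) * sign(proj$n))
  phi <- proj$G - rho / proj$radius
  lam <- theta / proj$n
  data.frame(lon = proj$lon0 + lam * 180 / pi, lat = phi * 180 / pi)
}

#' Project fix coordinates to planar meters
#'
#' Adds `x` and `y` columns (meters in the analysis projection) to a fix
#' table holding `lon` and `lat` in decimal degrees.
#'
#' @param fixes A data.frame with `lon` and `lat` columns.
#' @param proj An [eqc_projection()]; the default uses standard parallels
#'   at 33 and 45 deg N.
#' @return `fixes` with `x`, `y` columns added (meters).
#' @export
project_fixes <- function(fixes, proj = eqc_projection()) {
  xy <- eqc_forward(proj, fixes$lon, fixes$lat)
  fixes$x <- xy$x
  fixes$y <- xy$y
  fixes
}
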