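# Planar projection, polygon geometry and GeoJSON interchange.
#
# Internally all geometry is planar metres. Interchange files carry WGS84
# lon/lat; conversion goes through a local equirectangular projection whose
# origin is declared alongside the data, so round-trips are exact to floating
# point and distances near the origin are accurate to well under 0.5 m over a
# study-area-sized extent.

# WGS84 ellipsoid
.WGS84_A <- 6378137
.WGS84_F <- 1 / 298.257223563
.WGS84_E2 <- .WGS84_F * (2 - .WGS84_F)

#' Local planar projection
#'
#' Defines an ellipsoidal equirectangular projection centred on a declared
#' origin: eastings scale with the normal radius of curvature at the origin
#' latitude, northings with the meridional radius. The map is affine in
#' lon/lat and therefore exactly invertible; distortion grows quadratically
#' with distance from the origin and is negligible over a study area of a few
#' hundred square kilometres.
#'
#' @param lon0,lat0 Origin of the projection in WGS84 decimal degrees.
#' @return An object of class `roost_projection` holding the origin and the
#'   metres-per-degree scale factors.
#' @examples
#' prj <- local_projection(7.0, 46.8)
#' xy <- project_lonlat(cbind(7.01, 46.81), prj)
#' unproject_xy(xy, prj)
#' @export
local_projection <- function(lon0, lat0) {
  stopifnot(is.finite(lon0), is.finite(lat0), abs(lat0) < 89)
  phi <- lat0 * pi / 180
  s2 <- sin(phi)^2
  nrad <- .WGS84_A / sqrt(1 - .WGS84_E2 * s2)
  mrad <- .WGS84_A * (1 - .WGS84_E2) / (1 - .WGS84_E2 * s2)^1.5
  structure(
    list(lon0 = lon0, lat0 = lat0,
         mx = nrad * cos(phi) * pi / 180,  # metres per degree longitude
         my = mrad * pi / 180),            # metres per degree latitude
    class = "roost_projection")
}

#' @export
print.roost_projection <- function(x, ...) {
  cat(sprintf("Local equirectangular projection, origin %.5f E %.5f N (WGS84)\n",
              x$lon0, x$lat0))
  invisible(x)
}

#' Project WGS84 coordinates to planar metres
#'
#' @param lonlat Two-column matrix or data.frame of longitude, latitude
#'   (decimal degrees).
#' @param projection A [local_projection()] object.
#' @return Two-column matrix of x (east), y (north) in metres.
#' @export
project_lonlat <- function(lonlat, projection) {
  stopifnot(inherits(projection, "roost_projection"))
  lonlat <- as.matrix(lonlat)
  if (ncol(lonlat) != 2) stop("lonlat must have two columns (lon, lat)")
  if (any(!is.finite(lonlat))) stop("non-finite coordinates")
  if (any(abs(lonlat[, 2]) > 90) || any(abs(lonlat[, 1]) > 360))
    stop("coordinates outside WGS84 validity")
  cbind(x = (lonlat[, 1] - projection$lon0) * projection$mx,
        y = (lonlat[, 2] - projection$lat0) * projection$my)
}

#' Inverse of [project_lonlat()]
#'
#' @param xy Two-column matrix of planar x, y in metres.
#' @param projection A [local_projection()] object.
#' @return Two-column matrix of lon, lat.
#' @export
unproject_xy <- function(xy, projection) {
  stopifnot(inherits(projection, "roost_projection"))
  xy <- as.matrix(xy)
  cbind(lon = xy[, 1] / projection$mx + projection$lon0,
        lat = xy[, 2] / projection$my + projection$lat0)
}

#' Project raw GPS fixes
#'
#' Adds planar `x`, `y` columns (metres) to a fix table and records the
#' projection used as an attribute, so downstream outputs can declare their
#' provenance.
#'
#' @param fixes Data frame with `lon` and `lat` columns (WGS84 degrees).
#' @param projection A [local_projection()] object.
#' @return `fixes` with `x`, `y` columns appended and attribute `projection`.
#' @export
project_coordinates <- function(fixes, projection) {
  xy <- project_lonlat(fixes[, c("lon", "lat")], projection)
  fixes$x <- xy[, 1]
  fixes$y <- xy[, 2]
  attr(fixes, "projection") <- projection
  fixes
}

## ---- polygon geometry ----------------------------------------------------

#' Test points for inclusion in a polygon
#'
#' Ray-casting (even-odd) rule; points exactly on the boundary count as
#' inside.
#'
#' @param xy Two-column matrix of points (planar metres).
#' @param polygon Two-column matrix of polygon vertices (closed or open ring).
#' @return Logical vector.
#' @export
point_in_polygon <- function(xy, polygon) {
  xy <- as.matrix(xy)
  poly <- .close_ring(polygon)
  n <- nrow(poly) - 1L
  px <- xy[, 1]; py <- xy[, 2]
  inside <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    x1 <- poly[i, 1]; y1 <- poly[i, 2]
    x2 <- poly[i + 1, 1]; y2 <- poly[i + 1, 2]
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
  }
  # boundary points count as inside
  on_edge <- .point_segment_dist_min(xy, poly) < 1e-9
  inside | on_edge
}

#' Distance from points to a polygon boundary
#'
#' Returns 0 for points inside (or on) the polygon, otherwise the Euclidean
#' distance to the nearest boundary segment.
#'
#' @inheritParams point_in_polygon
#' @return Numeric vector of distances (metres).
#' @export
distance_to_polygon <- function(xy, polygon) {
  xy <- as.matrix(xy)
  d <- .point_segment_dist_min(xy, .close_ring(polygon))
  d[point_in_polygon(xy, polygon)] <- 0
  d
}

.close_ring <- function(polygon) {
  poly <- as.matrix(polygon)
  if (nrow(poly) < 3) stop("degenerate polygon: fewer than 3 vertices")
  if (any(poly[1, ] != poly[nrow(poly), ])) poly <- rbind(poly, poly[1, ])
  if (abs(.ring_area(poly)) < 1e-6) stop("degenerate polygon: zero area")
  poly
}

.ring_area <- function(poly) {
  n <- nrow(poly)
  sum(poly[-n, 1] * poly[-1, 2] - poly[-1, 1] * poly[-n, 2]) / 2
}

# min distance from each point to any segment of a closed ring
.point_segment_dist_min <- function(xy, ring) {
  n <- nrow(ring) - 1L
  dmin <- rep(Inf, nrow(xy))
  for (i in seq_len(n)) {
    a <- ring[i, ]; b <- ring[i + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) next
    t <- ((xy[, 1] - a[1]) * ab[1] + (xy[, 2] - a[2]) * ab[2]) / len2
    t <- pmin(pmax(t, 0), 1)
    dx <- a[1] + t * ab[1] - xy[, 1]
    dy <- a[2] + t * ab[2] - xy[, 2]
    dmin <- pmin(dmin, sqrt(dx^2 + dy^2))
  }
  dmin
}

## ---- GeoJSON -------------------------------------------------------------

#' Read a GeoJSON polygon
#'
#' Accepts a `Polygon` geometry, a `Feature` wrapping one, or a
#' `FeatureCollection` whose first feature is one. Only the outer ring is
#' used.
#'
#' @param path Path to a GeoJSON file (WGS84).
#' @return Two-column matrix of lon, lat vertices (open ring).
#' @export
read_geojson_polygon <- function(path) {
  g <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  geom <- switch(g$type,
    Polygon = g,
    Feature = g$geometry,
    FeatureCollection = {
      gm <- g$features$geometry
      list(type = gm$type[[1]], coordinates = gm$coordinates[[1]])
    },
    stop("unsupported GeoJSON type: ", g$type))
  if (geom$type != "Polygon") stop("geometry is not a Polygon")
  ring <- geom$coordinates
  if (is.list(ring)) ring <- ring[[1]]
  if (length(dim(ring)) == 3) ring <- ring[1, , ]
  ring <- as.matrix(ring)
  colnames(ring) <- c("lon", "lat")
  if (all(ring[1, ] == ring[nrow(ring), ])) ring <- ring[-nrow(ring), , drop = FALSE]
  ring
}

#' Write a polygon as GeoJSON
#'
#' @param lonlat Two-column matrix of lon, lat vertices (open ring).
#' @param path Output path.
#' @export
write_geojson_polygon <- function(lonlat, path) {
  ring <- as.matrix(lonlat)
  ring <- rbind(ring, ring[1, ])  # GeoJSON rings are closed
  obj <- list(type = "Polygon", coordinates = list(ring))
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = 8)
  writeLines(txt, path)
  invisible(path)
}
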