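#' Azimuthal equidistant projection
#'
#' Forward and inverse spherical azimuthal equidistant projection used to move
#' between geographic coordinates (degrees) and planar track coordinates (km).
#' The default centre (40 degrees W, 45 degrees S) keeps distances faithful
#' across the 15-65 degrees S span of a Brazil-to-Southern-Ocean migration.
#'
#' @param lon,lat numeric vectors, degrees.
#' @param proj projection spec from [aeqd_projection()].
#' @param x,y numeric vectors, planar km.
#' @return `project_lonlat()` returns a two-column matrix (`x`, `y`) in km;
#'   `unproject_xy()` a two-column matrix (`lon`, `lat`) in degrees.
#' @examples
#' p <- aeqd_projection()
#' xy <- project_lonlat(-40, -45, p)   # centre maps to the origin
#' unproject_xy(xy[, 1], xy[, 2], p)
#' @export
aeqd_projection <- function(lon0 = -40, lat0 = -45, radius_km = 6371) {
  stopifnot(is.finite(lon0), is.finite(lat0), radius_km > 0)
  structure(list(lon0 = lon0, lat0 = lat0, R = radius_km),
            class = "aeqd_projection")
}

#' @rdname aeqd_projection
#' @export
project_lonlat <- function(lon, lat, proj = aeqd_projection()) {
  stopifnot(inherits(proj, "aeqd_projection"), length(lon) == length(lat))
  if (any(!is.finite(lon) | !is.finite(lat)) ||
      any(lat < -90 | lat > 90)) {
    stop("invalid lon/lat passed to project_lonlat()")
  }
  d2r <- pi / 180
  phi <- lat * d2r; phi0 <- proj$lat0 * d2r
  dl <- (lon - proj$lon0) * d2r
  cosc <- sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(dl)
  cosc <- pmin(1, pmax(-1, cosc))
  c_ang <- acos(cosc)
  # antipode of the centre is outside the projection's validity
  if (any(c_ang > pi - 1e-9)) stop("point at or near projection antipode")
  k <- ifelse(c_ang < 1e-12, 1, c_ang / sin(c_ang)) * proj$R
  x <- k * cos(phi) * sin(dl)
  y <- k * (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(dl))
  cbind(x = x, y = y)
}

#' @rdname aeqd_projection
#' @export
unproject_xy <- function(x, y, proj = aeqd_projection()) {
  stopifnot(inherits(proj, "aeqd_projection"), length(x) == length(y))
  d2r <- pi / 180
  phi0 <- proj$lat0 * d2r
  rho <- sqrt(x^2 + y^2)
  c_ang <- rho / proj$R
  sinc <- sin(c_ang); cosc <- cos(c_ang)
  phi <- ifelse(rho < 1e-12, phi0,
                asin(pmin(1, pmax(-1, cosc * sin(phi0) + y * sinc * cos(phi0) / rho))))
  lam <- ifelse(rho < 1e-12, 0,
                atan2(x * sinc, rho * cos(phi0) * cosc - y * sin(phi0) * sinc))
  lon <- proj$lon0 + lam / d2r
  lon <- ((lon + 180) %% 360) - 180
  cbind(lon = lon, lat = phi / d2r)
}

#' Point-in-polygon test (ray casting)
#'
#' Even-odd ray casting in lon/lat space; adequate for the coarse regional
#' polygons (continental-shelf masks) used for track censoring.  Points on an
#' edge may land on either side; censoring polygons are buffered well away
#' from the data so this does not matter in practice.
#'
#' @param lon,lat point coordinates, degrees.
#' @param polygon two-column matrix of vertices (lon, lat), open or closed.
#' @return logical vector.
#' @export
point_in_polygon <- function(lon, lat, polygon) {
  polygon <- as.matrix(polygon)
  stopifnot(ncol(polygon) == 2, nrow(polygon) >= 3)
  px <- polygon[, 1]; py <- polygon[, 2]
  n <- length(px)
  inside <- logical(length(lon))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((py[i] > lat) != (py[j] > lat)) &
      (lon < (px[j] - px[i]) * (lat - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, crosses & !is.na(crosses))
    j <- i
  }
  inside
}

#' Read and write simple GeoJSON geometries
#'
#' Minimal GeoJSON support for the two geometry kinds the analysis needs: a
#' `Polygon` (shelf mask) and a `LineString` (oceanographic front).  Returns a
#' two-column coordinate matrix; only the outer ring of a polygon is kept.
#'
#' @param path file path.
#' @return two-column matrix of (lon, lat) vertices with attribute
#'   `geometry_type`.
#' @export
read_geojson_coords <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(g$features)) g <- g$features$geometry # FeatureCollection: first geometry set
  type <- if (is.data.frame(g)) g$type[1] else g$type
  coords <- if (is.data.frame(g)) g$coordinates[[1]] else g$coordinates
  if (identical(type, "Polygon")) {
    m <- if (is.list(coords)) coords[[1]] else coords[1, , ]
  } else if (identical(type, "LineString")) {
    m <- coords
  } else {
    stop("unsupported GeoJSON geometry type: ", type)
  }
  m <- matrix(as.numeric(as.matrix(m)), ncol = 2,
              dimnames = list(NULL, c("lon", "lat")))
  structure(m, geometry_type = type)
}

#' @rdname read_geojson_coords
#' @param coords two-column matrix (lon, lat).
#' @param type `"Polygon"` or `"LineString"`.
#' @export
write_geojson_coords <- function(coords, type = c("Polygon", "LineString"), path) {
  type <- match.arg(type)
  coords <- as.matrix(coords)
  if (type == "Polygon" &&
      !isTRUE(all.equal(coords[1, ], coords[nrow(coords), ], check.attributes = FALSE))) {
    coords <- rbind(coords, coords[1, ]) # close the ring
  }
  cl <- lapply(seq_len(nrow(coords)), function(i) c(coords[i, 1], coords[i, 2]))
  geom <- if (type == "Polygon") list(type = type, coordinates = list(cl)) else
    list(type = type, coordinates = cl)
  jsonlite::write_json(geom, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
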