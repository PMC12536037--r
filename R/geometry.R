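#' Local tangent-plane projection
#'
#' All metric computations in pmtrace happen in a local planar projection
#' about a fixed origin (typically the region centroid), because distances
#' in raw lon/lat degrees are anisotropic. The projection is the exactly
#' invertible equirectangular tangent plane: `x = R cos(lat0) dlon`,
#' `y = R dlat` (radians), adequate at study scales of a few tens of km.
#'
#' @param lon,lat numeric vectors of WGS84 coordinates (degrees).
#' @param origin length-2 numeric `c(lon0, lat0)` of the projection origin.
#' @return `project_lonlat()`: a tibble with columns `x`, `y` in metres.
#'   `unproject_xy()`: a tibble with columns `lon`, `lat` in degrees.
#' @export
project_lonlat <- function(lon, lat, origin) {
  stopifnot(length(origin) == 2, is.finite(origin))
  r <- 6371008.8 # mean Earth radius, m
  tibble::tibble(
    x = r * cos(origin[2] * pi / 180) * (lon - origin[1]) * pi / 180,
    y = r * (lat - origin[2]) * pi / 180
  )
}

#' @rdname project_lonlat
#' @param x,y numeric vectors of projected coordinates (metres).
#' @export
unproject_xy <- function(x, y, origin) {
  stopifnot(length(origin) == 2, is.finite(origin))
  r <- 6371008.8
  tibble::tibble(
    lon = origin[1] + (x / (r * cos(origin[2] * pi / 180))) * 180 / pi,
    lat = origin[2] + (y / r) * 180 / pi
  )
}

# Ray-casting point-in-polygon for a single ring given as a 2-column matrix
# (open ring: first vertex not repeated). Points on the boundary count as
# inside (distance-0 convention used by the nearest-feature join).
point_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  xs <- ring[, 1]; ys <- ring[, 2]
  xe <- xs[c(2:n, 1)]; ye <- ys[c(2:n, 1)]
  inside <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    crosses <- ((ys[i] > py) != (ye[i] > py))
    xint <- xs[i] + (py - ys[i]) / (ye[i] - ys[i]) * (xe[i] - xs[i])
    flip <- crosses & (px < xint)
    inside <- xor(inside, ifelse(is.na(flip), FALSE, flip))
  }
  inside
}

# Distance from points to a segment (x1,y1)-(x2,y2), vectorised over points.
dist_point_segment <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return(sqrt((px - x1)^2 + (py - y1)^2))
  t <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / len2))
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

# Distance from points to a polygon ring boundary; 0 for interior points.
dist_point_ring <- function(px, py, ring) {
  n <- nrow(ring)
  d <- rep(Inf, length(px))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    d <- pmin(d, dist_point_segment(px, py, ring[i, 1], ring[i, 2],
                                    ring[j, 1], ring[j, 2]))
  }
  d[point_in_ring(px, py, ring)] <- 0
  d
}

#' Nearest polygon feature for a set of points
#'
#' Assigns each point the feature whose polygon is nearest (distance 0 if
#' the point lies inside it). Ties are broken by the smallest feature index
#' so the join is deterministic.
#'
#' @param px,py numeric vectors, projected point coordinates (metres).
#' @param features a tibble with a list-column `geometry` of 2-column
#'   coordinate matrices (one ring per feature).
#' @return a tibble with columns `feature` (row index into `features`) and
#'   `distance` (metres).
#' @export
nearest_feature <- function(px, py, features) {
  stopifnot(nrow(features) > 0)
  best_d <- rep(Inf, length(px))
  best_i <- rep(NA_integer_, length(px))
  for (i in seq_len(nrow(features))) {
    d <- dist_point_ring(px, py, features$geometry[[i]])
    upd <- d < best_d # strict: earlier feature wins ties
    best_d[upd] <- d[upd]
    best_i[upd] <- i
  }
  tibble::tibble(feature = best_i, distance = best_d)
}

# Minimum distance from points to any feature in a layer (e.g. buildings).
min_dist_to_layer <- function(px, py, features) {
  if (nrow(features) == 0) return(rep(Inf, length(px)))
  nearest_feature(px, py, features)$distance
}

# Axis-aligned rectangle ring centred at (cx, cy).
rect_ring <- function(cx, cy, w, h) {
  cbind(
    x = c(cx - w / 2, cx + w / 2, cx + w / 2, cx - w / 2),
    y = c(cy - h / 2, cy - h / 2, cy + h / 2, cy + h / 2)
  )
}
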