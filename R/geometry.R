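# Spherical and planar geometry primitives shared by the exposure estimators.
# All great-circle math is spherical with R = 6371.0088 km; metre-true buffer
# work happens in a local azimuthal equidistant projection centred on each fix.

EARTH_RADIUS_M <- 6371008.8

#' Great-circle distance in metres
#'
#' Haversine distance on a sphere of radius 6371.0088 km. Inputs are recycled;
#' either side may be a single point or a set of points.
#'
#' @param lon1,lat1 Coordinates of the first point(s), decimal degrees WGS84.
#' @param lon2,lat2 Coordinates of the second point(s).
#' @return Numeric vector of distances in metres.
#' @export
haversine_m <- function(lon1, lat1, lon2, lat2) {
  n <- max(length(lon1), length(lon2))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_M)
}

#' Project points into a local azimuthal equidistant plane
#'
#' Maps lon/lat points to planar x/y metres about a centre point. Distances
#' from the centre are exact (azimuthal equidistant), which is what disc
#' buffers need.
#'
#' @param lon,lat Points to project (degrees).
#' @param lon0,lat0 Projection centre (degrees).
#' @return A two-column matrix (x, y) in metres; (0, 0) is the centre.
#' @export
local_aeq <- function(lon, lat, lon0, lat0) {
  n <- length(lon)
  if (n == 0L) return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("x", "y"))))
  p <- cbind(lon, lat)
  c0 <- cbind(rep(lon0, n), rep(lat0, n))
  d <- geosphere::distHaversine(c0, p, r = EARTH_RADIUS_M)
  # spherical initial bearing, consistent with the haversine distance above
  la1 <- lat0 * pi / 180; la2 <- lat * pi / 180
  dlo <- (lon - lon0) * pi / 180
  b <- atan2(sin(dlo) * cos(la2),
             cos(la1) * sin(la2) - sin(la1) * cos(la2) * cos(dlo))
  b[is.na(b) | d == 0] <- 0 # coincident with centre
  cbind(x = d * sin(b), y = d * cos(b))
}

#' Point-in-polygon test (ray casting)
#'
#' Even-odd ray-casting containment test in the lon/lat plane. Rings need not
#' be closed; holes (rings beyond the first) flip containment.
#'
#' @param lon,lat Query point.
#' @param rings A list of rings, each a two-column matrix of lon/lat vertices.
#' @return Logical scalar.
#' @export
point_in_polygon <- function(lon, lat, rings) {
  inside <- FALSE
  for (ring in rings) {
    if (ray_cast(lon, lat, ring)) inside <- !inside
  }
  inside
}

ray_cast <- function(px, py, ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if (((y[i] > py) != (y[j] > py)) &&
        (px < (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i])) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

#' Minimum distance from a point to a polygon boundary, in metres
#'
#' Projects the polygon's outer ring into a local plane about the point and
#' takes the minimum point-to-segment distance. Returns 0 when inside.
#'
#' @param lon,lat Query point (degrees).
#' @param rings Polygon rings as in [point_in_polygon()].
#' @return Distance in metres (0 if the point is contained).
#' @export
dist_to_polygon_m <- function(lon, lat, rings) {
  if (point_in_polygon(lon, lat, rings)) return(0)
  dmin <- Inf
  for (ring in rings) {
    xy <- local_aeq(ring[, 1], ring[, 2], lon, lat)
    n <- nrow(xy)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      dmin <- min(dmin, dist_point_segment(0, 0, xy[i, 1], xy[i, 2], xy[j, 1], xy[j, 2]))
    }
  }
  dmin
}

dist_point_segment <- function(px, py, ax, ay, bx, by) {
  abx <- bx - ax; aby <- by - ay
  len2 <- abx^2 + aby^2
  t <- if (len2 == 0) 0 else max(0, min(1, ((px - ax) * abx + (py - ay) * aby) / len2))
  sqrt((ax + t * abx - px)^2 + (ay + t * aby - py)^2)
}

#' Length of a planar segment clipped to a disc centred at the origin
#'
#' Closed-form intersection of the segment (a, b) with the disc of radius `r`
#' about (0, 0); used to accumulate road length inside a buffer.
#'
#' @param ax,ay,bx,by Segment endpoints (planar metres).
#' @param r Disc radius in metres.
#' @return Clipped length in metres (0 when the segment misses the disc).
#' @export
clip_segment_to_disc <- function(ax, ay, bx, by, r) {
  dx <- bx - ax; dy <- by - ay
  a <- dx^2 + dy^2
  if (a == 0) return(0)
  b <- 2 * (ax * dx + ay * dy)
  cc <- ax^2 + ay^2 - r^2
  disc <- b^2 - 4 * a * cc
  if (disc <= 0) return(0)
  sq <- sqrt(disc)
  t1 <- max((-b - sq) / (2 * a), 0)
  t2 <- min((-b + sq) / (2 * a), 1)
  if (t2 <= t1) return(0)
  (t2 - t1) * sqrt(a)
}
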