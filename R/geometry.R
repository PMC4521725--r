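# Planar geometry helpers (km coordinate frame). Polygons are n x 2 matrices
# of vertices in order; the closing edge last->first is implicit.

#' Observed home-range centre of a set of trap locations
#'
#' Computes the centroid of the 100% minimum convex polygon around the traps
#' at which an individual was detected. Degenerate inputs follow the field
#' convention: a single trap returns that trap location, two traps return
#' their midpoint, and collinear point sets fall back to the mean of the
#' unique points. For three or more non-collinear points the area centroid of
#' the convex hull is returned (not the vertex mean).
#'
#' @param points numeric matrix (n x 2) of trap coordinates in km.
#' @return numeric length-2 vector `c(x, y)`.
#' @export
observed_centre <- function(points) {
  points <- rbind(points)
  storage.mode(points) <- "double"
  if (nrow(points) == 0L) stop("observed_centre: no trap locations supplied")
  if (ncol(points) != 2L) stop("observed_centre: points must have two columns")
  pts <- unique(points)
  if (nrow(pts) == 1L) return(c(pts[1, 1], pts[1, 2]))
  if (nrow(pts) == 2L) return(colMeans(pts))
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  a2 <- polygon_signed_area2(hull)
  if (abs(a2) < 1e-12) return(colMeans(pts))  # collinear
  polygon_centroid(hull)
}

# twice the signed area (shoelace)
polygon_signed_area2 <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y)
}

#' Area of a polygon
#' @param poly numeric matrix (n x 2) of vertices in order.
#' @return area in squared coordinate units.
#' @export
polygon_area <- function(poly) abs(polygon_signed_area2(poly)) / 2

# area centroid of a simple polygon
polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a2 <- sum(cr)
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (3 * a2)
}

#' Point-in-polygon test
#'
#' Ray-casting test; points exactly on the boundary count as inside.
#'
#' @param point numeric length-2 vector.
#' @param poly numeric matrix (n x 2) of polygon vertices.
#' @return logical.
#' @export
point_in_polygon <- function(point, poly) {
  px <- point[1]; py <- point[2]
  n <- nrow(poly)
  if (distance_to_boundary(point, poly) < 1e-9) return(TRUE)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py)) {
      xcross <- xi + (py - yi) / (yj - yi) * (xj - xi)
      if (px < xcross) inside <- !inside
    }
    j <- i
  }
  inside
}

# minimum distance from a point to the polygon outline (any position)
distance_to_boundary <- function(point, poly) {
  n <- nrow(poly)
  nxt <- c(seq_len(n)[-1], 1L)
  ax <- poly[, 1]; ay <- poly[, 2]
  bx <- poly[nxt, 1]; by <- poly[nxt, 2]
  dx <- bx - ax; dy <- by - ay
  len2 <- dx^2 + dy^2
  tt <- ((point[1] - ax) * dx + (point[2] - ay) * dy) / pmax(len2, 1e-300)
  tt <- pmin(pmax(tt, 0), 1)
  qx <- ax + tt * dx; qy <- ay + tt * dy
  sqrt(min((point[1] - qx)^2 + (point[2] - qy)^2))
}

#' Distance from a home-range centre to the study-area edge (DEDGE)
#'
#' Euclidean distance from a point inside the study boundary to the nearest
#' boundary segment. Used as the DEDGE detection covariate: animals whose
#' range centres sit near the edge are exposed to fewer traps.
#'
#' @param point numeric length-2 vector (km), inside or on the boundary.
#' @param boundary numeric matrix (n x 2) of polygon vertices (km).
#' @return nonnegative distance in km.
#' @export
distance_to_edge <- function(point, boundary) {
  if (!point_in_polygon(point, boundary)) {
    stop(sprintf(
      "distance_to_edge: point (%.3f, %.3f) lies outside the study boundary",
      point[1], point[2]))
  }
  distance_to_boundary(point, boundary)
}

#' Rectangular boundary from trap locations plus a buffer
#'
#' Builds an axis-aligned rectangle enclosing all trap locations expanded by
#' `buffer` km on every side. This is the state-space/study-boundary
#' convention used for the simulated square-grid design (trap grid plus a
#' 2.5-spacing buffer) and the default when a boundary is requested as
#' `"buffer:<km>"`.
#'
#' @param xy numeric matrix (n x 2) of trap coordinates.
#' @param buffer buffer width in km.
#' @return 4 x 2 matrix of rectangle vertices (counter-clockwise).
#' @export
buffer_rectangle <- function(xy, buffer) {
  stopifnot(buffer > 0)
  xr <- range(xy[, 1]) + c(-buffer, buffer)
  yr <- range(xy[, 2]) + c(-buffer, buffer)
  cbind(x = c(xr[1], xr[2], xr[2], xr[1]),
        y = c(yr[1], yr[1], yr[2], yr[2]))
}
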