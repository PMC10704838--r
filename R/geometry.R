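# Low-level planar geometry for polygonal profiles.
#
# Polygons are two-column matrices (x, y) of vertices in order, *without* a
# repeated closing vertex. Units are whatever the caller uses (um for light
# microscopy, nm for TEM); all functions are unit-agnostic.

GEOM_TOL <- 1e-9

as_polygon <- function(p) {
  p <- as.matrix(p)
  if (ncol(p) != 2 || nrow(p) < 3) stop("polygon must be an n x 2 matrix with n >= 3")
  storage.mode(p) <- "double"
  unname(p)
}

#' Signed polygon area (shoelace formula)
#'
#' Positive for counter-clockwise vertex order.
#'
#' @param poly n x 2 vertex matrix, unclosed.
#' @return Signed area in squared input units.
#' @keywords internal
polygon_area_signed <- function(poly) {
  poly <- as_polygon(poly)
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

#' Polygon area (absolute, shoelace)
#' @inheritParams polygon_area_signed
#' @return Area (>= 0).
#' @export
polygon_area <- function(poly) abs(polygon_area_signed(poly))

#' Polygon perimeter (closed polyline length)
#' @inheritParams polygon_area_signed
#' @return Perimeter length.
#' @export
polygon_perimeter <- function(poly) {
  poly <- as_polygon(poly)
  d <- poly[c(2:nrow(poly), 1), ] - poly
  sum(sqrt(rowSums(d^2)))
}

#' Polygon centroid (area-weighted)
#' @inheritParams polygon_area_signed
#' @return Length-2 numeric (x, y).
#' @keywords internal
polygon_centroid <- function(poly) {
  poly <- as_polygon(poly)
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  cr <- x * ys - xs * y
  a <- sum(cr) / 2
  if (abs(a) < GEOM_TOL) return(colMeans(poly))
  c(sum((x + xs) * cr), sum((y + ys) * cr)) / (6 * a)
}

#' Test points for inclusion in a polygon (boundary counts as inside)
#'
#' @param x,y coordinates of query points.
#' @param poly n x 2 vertex matrix.
#' @return Logical vector.
#' @keywords internal
points_in_polygon <- function(x, y, poly) {
  poly <- as_polygon(poly)
  pracma::inpolygon(x, y, poly[, 1], poly[, 2], boundary = TRUE)
}

# Fast even-odd (crossing number) point-in-polygon, vectorized over points.
# Boundary points are not handled specially; use points_in_polygon where
# boundary inclusion matters.
points_in_polygon_fast <- function(x, y, poly) {
  px <- poly[, 1]; py <- poly[, 2]
  n <- length(px)
  jx <- c(px[n], px[-n]); jy <- c(py[n], py[-n])
  inside <- rep(FALSE, length(x))
  for (k in seq_len(n)) {
    xi <- px[k]; yi <- py[k]; xj <- jx[k]; yj <- jy[k]
    if (yi == yj) next
    cross <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
  }
  inside
}

# Convex hull of the vertex set, as an index-ordered matrix.
convex_hull <- function(poly) {
  poly <- as_polygon(poly)
  poly[grDevices::chull(poly[, 1], poly[, 2]), , drop = FALSE]
}

#' Maximum caliper (Feret) diameter of a polygon
#' @inheritParams polygon_area_signed
#' @return Largest point-to-point distance over the convex hull.
#' @export
max_caliper_diameter <- function(poly) {
  h <- convex_hull(poly)
  sqrt(max(as.matrix(stats::dist(h))^2))
}

#' Minimal Feret diameter of a polygon
#'
#' Smallest width over all rotations, computed over the convex hull: for each
#' hull edge direction the projection width onto the edge normal is taken and
#' the minimum returned. This is the standard "minimal caliper" used for
#' muscle-fiber diameters because it is robust to oblique sectioning.
#'
#' @inheritParams polygon_area_signed
#' @return Minimal caliper width.
#' @export
min_feret_diameter <- function(poly) {
  h <- convex_hull(poly)
  n <- nrow(h)
  if (n < 3) return(0)
  e <- h[c(2:n, 1), ] - h
  len <- sqrt(rowSums(e^2))
  keep <- len > GEOM_TOL
  e <- e[keep, , drop = FALSE] / len[keep]
  # projection width onto every edge normal at once; max.col is the fast
  # row-wise argmax
  proj <- outer(-e[, 2], h[, 1]) + outer(e[, 1], h[, 2])  # edges x points
  i <- seq_len(nrow(proj))
  widths <- proj[cbind(i, max.col(proj))] - proj[cbind(i, max.col(-proj))]
  min(widths)
}

# Intersection of ray origin + t*dir (t > tol) with polygon boundary.
# Returns list(t, point, edge) for the nearest hit or NULL if none.
ray_polygon_intersection <- function(origin, dir, poly) {
  poly <- as_polygon(poly)
  n <- nrow(poly)
  a <- poly
  b <- poly[c(2:n, 1), , drop = FALSE]
  ex <- b[, 1] - a[, 1]; ey <- b[, 2] - a[, 2]
  dx <- dir[1]; dy <- dir[2]
  denom <- dx * ey - dy * ex
  ox <- a[, 1] - origin[1]; oy <- a[, 2] - origin[2]
  with_denom <- abs(denom) > GEOM_TOL
  t <- (ox * ey - oy * ex) / denom
  s <- (ox * dy - oy * dx) / denom
  ok <- with_denom & t > GEOM_TOL & s >= -GEOM_TOL & s <= 1 + GEOM_TOL
  if (!any(ok)) return(NULL)
  i <- which(ok)[which.min(t[ok])]
  list(t = t[i], point = origin + t[i] * dir, edge = i)
}

# Outward unit normal of polygon edge i (edge from vertex i to i+1), oriented
# away from the polygon centroid.
edge_outward_normal <- function(poly, i) {
  poly <- as_polygon(poly)
  n <- nrow(poly)
  a <- poly[i, ]; b <- poly[if (i == n) 1 else i + 1, ]
  e <- b - a
  nv <- c(e[2], -e[1])
  nv <- nv / sqrt(sum(nv^2))
  ctr <- polygon_centroid(poly)
  mid <- (a + b) / 2
  if (sum(nv * (mid - ctr)) < 0) nv <- -nv
  nv
}

# Closest point on the (closed) polygon boundary to point p.
# Returns list(point, dist).
closest_point_on_boundary <- function(p, poly) {
  poly <- as_polygon(poly)
  n <- nrow(poly)
  a <- poly
  b <- poly[c(2:n, 1), , drop = FALSE]
  ex <- b[, 1] - a[, 1]; ey <- b[, 2] - a[, 2]
  len2 <- ex^2 + ey^2
  t <- ((p[1] - a[, 1]) * ex + (p[2] - a[, 2]) * ey) / pmax(len2, GEOM_TOL)
  t <- pmin(pmax(t, 0), 1)
  qx <- a[, 1] + t * ex; qy <- a[, 2] + t * ey
  d2 <- (qx - p[1])^2 + (qy - p[2])^2
  i <- which.min(d2)
  list(point = c(qx[i], qy[i]), dist = sqrt(d2[i]))
}

# Proper/touching intersection test for two segments p1-p2, p3-p4 (inclusive
# of endpoints, tolerance GEOM_TOL).
segments_intersect <- function(p1, p2, p3, p4, tol = GEOM_TOL) {
  d1 <- p2 - p1; d2 <- p4 - p3
  denom <- d1[1] * d2[2] - d1[2] * d2[1]
  delta <- p3 - p1
  if (abs(denom) <= tol * (sum(abs(d1)) + sum(abs(d2)) + tol)) {
    # parallel: check collinear overlap
    cross <- delta[1] * d1[2] - delta[2] * d1[1]
    scale <- max(sqrt(sum(d1^2)), 1)
    if (abs(cross) > tol * scale) return(FALSE)
    # project onto the longer segment
    L2 <- sum(d1^2)
    if (L2 < tol^2) return(sqrt(sum((p1 - p3)^2)) <= tol || sqrt(sum((p1 - p4)^2)) <= tol)
    t3 <- sum((p3 - p1) * d1) / L2
    t4 <- sum((p4 - p1) * d1) / L2
    lo <- min(t3, t4); hi <- max(t3, t4)
    return(hi >= -tol && lo <= 1 + tol)
  }
  t <- (delta[1] * d2[2] - delta[2] * d2[1]) / denom
  u <- (delta[1] * d1[2] - delta[2] * d1[1]) / denom
  t >= -tol && t <= 1 + tol && u >= -tol && u <= 1 + tol
}

# Does the polygon boundary-or-interior touch segment p1-p2?
polygon_touches_segment <- function(poly, p1, p2, tol = GEOM_TOL) {
  poly <- as_polygon(poly)
  n <- nrow(poly)
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    if (segments_intersect(poly[i, ], poly[j, ], p1, p2, tol)) return(TRUE)
  }
  # segment entirely inside the polygon (no boundary crossing)
  any(points_in_polygon(c(p1[1], p2[1]), c(p1[2], p2[2]), poly))
}

# Fit-free aspect ratio: largest over smallest caliper diameter (>= 1).
caliper_aspect_ratio <- function(poly) {
  mf <- min_feret_diameter(poly)
  if (mf <= GEOM_TOL) stop("degenerate contour: zero minimal width")
  max_caliper_diameter(poly) / mf
}
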