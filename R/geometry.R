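# Planar geometry for contour-based quantification: shoelace areas,
# point-in-polygon rasterization and ray casting against polygon edges.
# Polygons are n x 2 matrices of (x, y) vertices, implicitly closed.

#' Signed-area-based polygon area (shoelace formula)
#'
#' @param poly Numeric matrix with two columns (x, y); the polygon is closed
#'   implicitly (last vertex connects back to the first).
#' @return Absolute enclosed area in squared input units.
#' @examples
#' polygon_area(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))  # unit square -> 1
#' @export
polygon_area <- function(poly) {
  poly <- as.matrix(poly)
  if (nrow(poly) < 3L) cmr_invalid("polygon needs at least 3 vertices")
  x <- poly[, 1L]; y <- poly[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  abs(sum(x * yn - xn * y)) / 2
}

#' Regular polygon approximation of a circle
#'
#' @param center Length-2 numeric (x, y).
#' @param radius Circle radius.
#' @param n Number of vertices (default 360).
#' @return An `n` x 2 vertex matrix traversed counterclockwise.
#' @export
circle_polygon <- function(center, radius, n = 360L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(center[1L] + radius * cos(th), center[2L] + radius * sin(th))
}

# Even-odd rule point-in-polygon test, vectorised over query points.
# Points exactly on an edge are resolved by the half-open crossing rule,
# which is the "center-in" rasterization convention used throughout.
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1L]; yi <- poly[i, 2L]
    xj <- poly[j, 1L]; yj <- poly[j, 2L]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# Distance from `center` to the first crossing of `poly` along direction
# `theta_deg` (degrees, counterclockwise from +x). Returns NA when the ray
# never meets the polygon (center outside, or numerical grazing).
ray_polygon_radius <- function(poly, center, theta_deg) {
  d <- c(cos(theta_deg * pi / 180), sin(theta_deg * pi / 180))
  p1 <- poly
  p2 <- poly[c(2:nrow(poly), 1L), , drop = FALSE]
  e <- p2 - p1
  # Solve center + r*d = p1 + u*e for each edge: 2x2 linear system.
  det <- d[1L] * (-e[, 2L]) - d[2L] * (-e[, 1L])
  rhs1 <- p1[, 1L] - center[1L]
  rhs2 <- p1[, 2L] - center[2L]
  ok <- abs(det) > 1e-12
  r <- (rhs1 * (-e[, 2L]) - rhs2 * (-e[, 1L])) / det
  u <- (d[1L] * rhs2 - d[2L] * rhs1) / det
  hit <- ok & r > 1e-9 & u >= 0 & u < 1
  if (!any(hit)) return(NA_real_)
  min(r[hit])
}

# TRUE when any two non-adjacent edges of the polygon cross (self-intersecting
# contours break the shoelace formula, so they are rejected up front).
polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  if (n < 4L) return(FALSE)
  a1 <- poly
  a2 <- poly[c(2:n, 1L), , drop = FALSE]
  seg_cross <- function(p, p2, q, q2) {
    d1 <- p2 - p; d2 <- q2 - q
    den <- d1[1L] * d2[2L] - d1[2L] * d2[1L]
    if (abs(den) < 1e-14) return(FALSE)
    t <- ((q[1L] - p[1L]) * d2[2L] - (q[2L] - p[2L]) * d2[1L]) / den
    u <- ((q[1L] - p[1L]) * d1[2L] - (q[2L] - p[2L]) * d1[1L]) / den
    t > 1e-10 && t < 1 - 1e-10 && u > 1e-10 && u < 1 - 1e-10
  }
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      if (seg_cross(a1[i, ], a2[i, ], a1[j, ], a2[j, ])) return(TRUE)
    }
  }
  FALSE
}

# Angle of voxel (row, col) about a center, in degrees in [0, 360),
# counterclockwise in anatomical orientation (image rows increase downward,
# so the row offset is negated). `origin_deg` rotates the zero reference to
# the anterior RV insertion point.
voxel_angles <- function(rows, cols, center_rc, origin_deg = 90) {
  ang <- atan2(-(rows - center_rc[1L]), cols - center_rc[2L]) * 180 / pi
  (ang - origin_deg) %% 360
}
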