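#' @useDynLib rosetteqtl, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- planar polygon utilities -------------------------------------------
# Polygons are matrices/data.frames with columns x, y; vertices in order,
# not repeated at the end. All routines are orientation-agnostic unless
# stated otherwise.

.poly_xy <- function(poly) {
  if (is.matrix(poly)) list(x = poly[, 1], y = poly[, 2]) else list(x = poly$x, y = poly$y)
}

#' Area of a simple polygon (shoelace formula)
#'
#' @param poly two-column matrix or list/data.frame with `x`, `y` vertex
#'   coordinates in traversal order (open ring).
#' @return Non-negative area.
#' @export
polygon_area <- function(poly) {
  p <- .poly_xy(poly)
  x <- p$x; y <- p$y
  n <- length(x)
  if (n < 3) return(0)
  i2 <- c(2:n, 1)
  abs(sum(x * y[i2] - x[i2] * y)) / 2
}

#' Perimeter of a closed polygon
#' @inheritParams polygon_area
#' @return Total edge length including the closing edge.
#' @export
polygon_perimeter <- function(poly) {
  p <- .poly_xy(poly)
  x <- p$x; y <- p$y
  n <- length(x)
  if (n < 2) return(0)
  i2 <- c(2:n, 1)
  sum(sqrt((x[i2] - x)^2 + (y[i2] - y)^2))
}

#' Centroid of a simple polygon
#' @inheritParams polygon_area
#' @return Numeric length-2 vector (x, y).
#' @export
polygon_centroid <- function(poly) {
  p <- .poly_xy(poly)
  x <- p$x; y <- p$y
  n <- length(x)
  i2 <- c(2:n, 1)
  w <- x * y[i2] - x[i2] * y
  a <- sum(w) / 2
  if (abs(a) < .Machine$double.eps) return(c(mean(x), mean(y)))
  c(sum((x + x[i2]) * w), sum((y + y[i2]) * w)) / (6 * a)
}

#' Second central moments of the region enclosed by a polygon
#'
#' Returns the per-unit-area central second moments (the covariance matrix of
#' a uniform density on the region), from which ellipse-equivalent axes are
#' derived.
#'
#' @inheritParams polygon_area
#' @return List with `area`, `centroid`, and 2x2 covariance matrix `cov`.
#' @export
polygon_moments <- function(poly) {
  p <- .poly_xy(poly)
  x <- p$x; y <- p$y
  n <- length(x)
  i2 <- c(2:n, 1)
  w <- x * y[i2] - x[i2] * y
  a <- sum(w) / 2
  if (abs(a) <= 0) stop("degenerate polygon: zero area")
  cx <- sum((x + x[i2]) * w) / (6 * a)
  cy <- sum((y + y[i2]) * w) / (6 * a)
  # raw second moments about the origin
  iyy <- sum(w * (x^2 + x * x[i2] + x[i2]^2)) / 12   # integral of x^2
  ixx <- sum(w * (y^2 + y * y[i2] + y[i2]^2)) / 12   # integral of y^2
  ixy <- sum(w * (x * y[i2] + 2 * x * y + 2 * x[i2] * y[i2] + x[i2] * y)) / 24
  varx <- iyy / a - cx^2
  vary <- ixx / a - cy^2
  covxy <- ixy / a - cx * cy
  list(area = abs(a), centroid = c(cx, cy),
       cov = matrix(c(varx, covxy, covxy, vary), 2, 2))
}

#' Ellipse-equivalent axes and eccentricity from a covariance matrix
#'
#' The ellipse with the same second moments as the region has full axes
#' `4 * sqrt(eigenvalue)`; eccentricity is `sqrt(1 - (minor/major)^2)`.
#'
#' @param cov 2x2 symmetric covariance matrix of the region.
#' @return List with `major`, `minor`, `eccentricity`.
#' @export
moment_axes <- function(cov) {
  ev <- eigen(cov, symmetric = TRUE)$values
  ev <- pmax(ev, 0)
  major <- 4 * sqrt(ev[1])
  minor <- 4 * sqrt(ev[2])
  ecc <- if (major <= 0) 0 else sqrt(max(0, major^2 - minor^2)) / major
  list(major = major, minor = minor, eccentricity = ecc)
}

#' Convex hull of a point set as an ordered polygon
#' @param x,y point coordinates.
#' @return Matrix with columns x, y (counter-clockwise hull vertices).
#' @export
convex_hull_polygon <- function(x, y) {
  idx <- rev(grDevices::chull(x, y))  # chull is clockwise; reverse to CCW
  cbind(x = x[idx], y = y[idx])
}

#' Exact area of the intersection of a polygon and a disk
#'
#' Decomposes the intersection into signed circle-triangle pieces, one per
#' polygon edge, each evaluated in closed form (triangle areas and circular
#' sectors). Exact up to floating point; no discretisation of the circle.
#' Edges must each subtend less than pi at the circle centre, which holds for
#' any polygon sampled at reasonable vertex density.
#'
#' @inheritParams polygon_area
#' @param center numeric length-2 circle centre.
#' @param r circle radius.
#' @return Non-negative intersection area.
#' @export
circle_polygon_intersection_area <- function(poly, center, r) {
  p <- .poly_xy(poly)
  x <- p$x - center[1]; y <- p$y - center[2]
  n <- length(x)
  if (n < 3 || r <= 0) return(0)
  i2 <- c(2:n, 1)
  total <- 0
  for (i in seq_len(n)) {
    total <- total + .circle_triangle_signed(c(x[i], y[i]), c(x[i2[i]], y[i2[i]]), r)
  }
  abs(total)
}

# Signed area of circle(origin, r) intersected with triangle (O, A, B),
# sign that of cross(A, B).
.circle_triangle_signed <- function(A, B, r) {
  cross <- function(u, v) u[1] * v[2] - u[2] * v[1]
  sector <- function(P, Q) {
    ang <- atan2(cross(P, Q), sum(P * Q))
    0.5 * r^2 * ang
  }
  na <- sqrt(sum(A^2)); nb <- sqrt(sum(B^2))
  a_in <- na <= r; b_in <- nb <= r
  if (a_in && b_in) return(cross(A, B) / 2)
  # segment-circle intersection: |A + t(B-A)|^2 = r^2
  D <- B - A
  qa <- sum(D^2); qb <- 2 * sum(A * D); qc <- sum(A^2) - r^2
  disc <- qb^2 - 4 * qa * qc
  if (a_in && !b_in) {
    t <- (-qb + sqrt(max(disc, 0))) / (2 * qa)
    X <- A + t * D
    return(cross(A, X) / 2 + sector(X, B))
  }
  if (!a_in && b_in) {
    t <- (-qb - sqrt(max(disc, 0))) / (2 * qa)
    X <- A + t * D
    return(sector(A, X) + cross(X, B) / 2)
  }
  # both endpoints outside
  if (disc > 0) {
    t1 <- (-qb - sqrt(disc)) / (2 * qa)
    t2 <- (-qb + sqrt(disc)) / (2 * qa)
    if (t1 > 0 && t2 < 1 && t1 < t2) {
      X1 <- A + t1 * D; X2 <- A + t2 * D
      return(sector(A, X1) + cross(X1, X2) / 2 + sector(X2, B))
    }
  }
  sector(A, B)
}

#' Area of a circular segment
#'
#' Region of a disk of radius `r` beyond a chord at distance `d` from the
#' centre.
#' @param r disk radius.
#' @param d chord distance from centre, `0 <= d <= r`.
#' @return Segment area.
#' @export
circular_segment_area <- function(r, d) {
  stopifnot(r > 0, d >= 0, d <= r)
  r^2 * acos(d / r) - d * sqrt(r^2 - d^2)
}

#' Area of an elliptic segment
#'
#' Region of an ellipse with semi-axes `a` (along x) and `b` beyond the chord
#' `x = d` (measured from the ellipse centre, `0 <= d <= a`). Obtained from
#' the circular segment by affine scaling.
#' @param a,b ellipse semi-axes.
#' @param d chord position along the a-axis.
#' @return Segment area.
#' @export
elliptic_segment_area <- function(a, b, d) {
  stopifnot(a > 0, b > 0, d >= 0, d <= a)
  m <- d / a
  a * b * (acos(m) - m * sqrt(1 - m^2))
}

#' Vertices of a regular polygon (testing helper for closed-form shapes)
#' @param n number of vertices.
#' @param r circumradius.
#' @param center centre of the polygon.
#' @param phase angular offset of the first vertex (radians).
#' @return Matrix with columns x, y.
#' @export
regular_polygon <- function(n, r = 1, center = c(0, 0), phase = 0) {
  th <- phase + 2 * pi * (seq_len(n) - 1) / n
  cbind(x = center[1] + r * cos(th), y = center[2] + r * sin(th))
}
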