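# Geometry and indexing helpers shared across the pipeline. All boundary
# polygons are n x 2 matrices of (x, y) coordinates in micrometres, ordered
# counterclockwise, open (last point != first point).

#' Cyclic index arithmetic
#'
#' Map arbitrary integer indices onto 1..n (boundary points are cyclic).
#'
#' @param i integer vector of (possibly out-of-range) indices.
#' @param n cycle length.
#' @return integer vector in 1..n.
#' @keywords internal
cyclic_index <- function(i, n) ((i - 1L) %% n) + 1L

#' Signed polygon area (shoelace formula)
#'
#' Positive for counterclockwise orientation.
#'
#' @param pts n x 2 coordinate matrix, open polygon.
#' @return signed area.
#' @keywords internal
polygon_area_signed <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

#' Polygon area (absolute)
#' @param pts n x 2 coordinate matrix.
#' @return area >= 0.
#' @keywords internal
polygon_area <- function(pts) abs(polygon_area_signed(pts))

#' Polygon centroid (area-weighted)
#' @param pts n x 2 coordinate matrix, open polygon.
#' @return length-2 numeric (x, y).
#' @keywords internal
polygon_centroid <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  cr <- x * ys - xs * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(colMeans(pts))
  c(sum((x + xs) * cr), sum((y + ys) * cr)) / (6 * a)
}

#' Ensure counterclockwise orientation
#' @param pts n x 2 coordinate matrix.
#' @return pts, reversed if it was clockwise.
#' @keywords internal
ensure_ccw <- function(pts) {
  if (polygon_area_signed(pts) < 0) pts[rev(seq_len(nrow(pts))), , drop = FALSE] else pts
}

#' Points-in-polygon test
#'
#' Thin wrapper around \code{mgcv::in.out}.
#'
#' @param poly m x 2 polygon (open).
#' @param pts n x 2 query points.
#' @return logical vector of length n.
#' @keywords internal
points_in_polygon <- function(poly, pts) {
  bnd <- rbind(poly, poly[1, , drop = FALSE])
  mgcv::in.out(bnd, matrix(as.numeric(pts), ncol = 2))
}

#' Resample a closed contour to evenly spaced points
#'
#' Linear interpolation along arc length; the first output point coincides
#' with the first input point, so callers anchor the start index before
#' resampling.
#'
#' @param pts m x 2 contour (open, ordered).
#' @param n number of output points.
#' @return n x 2 matrix with (near-)equal adjacent arc spacing.
#' @keywords internal
resample_closed_contour <- function(pts, n = 100L) {
  closed <- rbind(pts, pts[1, , drop = FALSE])
  seg <- sqrt(diff(closed[, 1])^2 + diff(closed[, 2])^2)
  keep <- c(TRUE, seg > .Machine$double.eps)
  closed <- closed[keep, , drop = FALSE]
  if (nrow(closed) < 4) stop("degenerate contour: fewer than 3 distinct points")
  seg <- sqrt(diff(closed[, 1])^2 + diff(closed[, 2])^2)
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  target <- total * (seq_len(n) - 1) / n
  x <- stats::approx(s, closed[, 1], xout = target)$y
  y <- stats::approx(s, closed[, 2], xout = target)$y
  cbind(x = x, y = y)
}

#' Unit vector
#' @param v length-2 numeric.
#' @return v / |v|, or c(NA, NA) if |v| is 0.
#' @keywords internal
unit_vector <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv < .Machine$double.eps) return(c(NA_real_, NA_real_))
  v / nv
}

#' Outward unit normals of a counterclockwise polygon
#'
#' Normal at point k from the central-difference tangent; for a CCW polygon
#' the outward normal is the tangent rotated by -90 degrees.
#'
#' @param pts n x 2 CCW polygon.
#' @return n x 2 matrix of unit normals.
#' @keywords internal
outward_normals <- function(pts) {
  n <- nrow(pts)
  tg <- pts[cyclic_index(seq_len(n) + 1L, n), , drop = FALSE] -
    pts[cyclic_index(seq_len(n) - 1L, n), , drop = FALSE]
  len <- sqrt(rowSums(tg^2))
  len[len < .Machine$double.eps] <- 1
  cbind(tg[, 2] / len, -tg[, 1] / len)
}
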