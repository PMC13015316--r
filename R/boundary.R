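# Per-point boundary kinematics: frame-to-frame point tracking with the
# minimum-displacement criterion, signed local motion and area change, and
# local curvature by the Pratt algebraic circle fit.

#' Track the 100 boundary points between consecutive frames
#'
#' Order-preserving cyclic assignment: the correspondence k -> k + s (mod n)
#' whose total squared displacement is minimal. Motion is signed positive
#' when the point moves outward from (i.e. ends up outside) the previous
#' frame's polygon, negative when it moves inward.
#'
#' @param prev,next_ n x 2 boundary matrices (um, CCW, same n).
#' @return list with \code{shift} (integer s), \code{correspondence}
#'   (index in \code{next_} for each point of \code{prev}) and \code{motion}
#'   (signed displacement per point, um).
#' @export
track_boundary_points <- function(prev, next_) {
  n <- nrow(prev)
  if (n != nrow(next_)) stop("boundaries must have the same number of points")
  if (polygon_area(prev) < .Machine$double.eps) stop("degenerate polygon")
  # total squared displacement for every cyclic shift
  costs <- vapply(0:(n - 1L), function(s) {
    idx <- cyclic_index(seq_len(n) + s, n)
    sum((next_[idx, ] - prev)^2)
  }, numeric(1))
  s <- which.min(costs) - 1L
  corr <- cyclic_index(seq_len(n) + s, n)
  moved <- next_[corr, , drop = FALSE]
  disp <- sqrt(rowSums((moved - prev)^2))
  outside <- !points_in_polygon(prev, moved)
  motion <- ifelse(disp < 1e-12, 0, ifelse(outside, disp, -disp))
  list(shift = s, correspondence = corr, motion = motion)
}

#' Signed local area change per boundary point
#'
#' For each point, the area of the hexagon whose vertices are the point in
#' the current and next frame plus the midpoints to its clockwise and
#' counterclockwise neighbours in both frames. Adjacent hexagons share their
#' connecting edges, so the signed areas tile the region swept by the
#' boundary exactly and their sum reproduces the total polygon area change;
#' the sign is taken from the hexagon's orientation (outward sweep positive,
#' agreeing with the sign of the point's motion in non-degenerate cases).
#' Self-intersecting local polygons are flagged and scored by the absolute
#' shoelace value with the motion's sign.
#'
#' @param prev,next_ n x 2 boundary matrices (um).
#' @param tracking result of \code{\link{track_boundary_points}} for this
#'   frame pair.
#' @return list with \code{area} (signed um^2 per point) and
#'   \code{self_intersecting} (logical flags).
#' @export
local_area_change <- function(prev, next_, tracking = track_boundary_points(prev, next_)) {
  n <- nrow(prev)
  corr <- tracking$correspondence
  motion <- tracking$motion
  a <- numeric(n); flag <- logical(n)
  for (k in seq_len(n)) {
    kc <- cyclic_index(k - 1L, n); ka <- cyclic_index(k + 1L, n)
    q <- corr[k]
    qc <- cyclic_index(q - 1L, n); qa <- cyclic_index(q + 1L, n)
    hexagon <- rbind((prev[k, ] + prev[kc, ]) / 2,
                     prev[k, ],
                     (prev[k, ] + prev[ka, ]) / 2,
                     (next_[q, ] + next_[qa, ]) / 2,
                     next_[q, ],
                     (next_[q, ] + next_[qc, ]) / 2)
    flag[k] <- polygon_self_intersects(hexagon)
    # traversal runs CCW along the old boundary and CW along the new one, so
    # an outward sweep encloses the strip clockwise: negate the shoelace
    a[k] <- if (flag[k]) polygon_area(hexagon) * sign(motion[k]) else
      -polygon_area_signed(hexagon)
  }
  list(area = a, self_intersecting = flag)
}

# simple O(m^2) test for non-adjacent edge crossings of a small polygon
polygon_self_intersects <- function(pts) {
  m <- nrow(pts)
  seg <- cbind(pts, pts[cyclic_index(seq_len(m) + 1L, m), , drop = FALSE])
  for (i in seq_len(m - 2L)) for (j in (i + 2L):m) {
    if (i == 1L && j == m) next
    if (segments_cross(seg[i, 1:2], seg[i, 3:4], seg[j, 1:2], seg[j, 3:4]))
      return(TRUE)
  }
  FALSE
}

segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2); d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

#' Pratt algebraic circle fit
#'
#' Fits a circle to points by minimizing the algebraic distance under
#' Pratt's normalization (b^2 + c^2 - 4*a*d = 1 for the conic
#' a(x^2+y^2) + bx + cy + d = 0), solved as a generalized eigenproblem.
#' Nearly collinear data give an infinite radius.
#'
#' @param pts m x 2 coordinate matrix (m >= 3).
#' @return list with \code{center} (x, y), \code{radius} (Inf when
#'   collinear).
#' @export
pratt_circle_fit <- function(pts) {
  mu <- colMeans(pts)
  x <- pts[, 1] - mu[1]; y <- pts[, 2] - mu[2]
  z <- x^2 + y^2
  Z <- cbind(z, x, y, 1)
  M <- crossprod(Z) / nrow(pts)
  B <- matrix(c(0, 0, 0, -2,
                0, 1, 0, 0,
                0, 0, 1, 0,
                -2, 0, 0, 0), 4, 4, byrow = TRUE)
  ev <- eigen(solve(B, M))
  eta <- Re(ev$values)
  vecs <- Re(ev$vectors)
  ok <- which(eta > -1e-12)
  if (!length(ok)) ok <- seq_along(eta)
  pick <- ok[which.min(eta[ok])]
  v <- vecs[, pick]
  scale2 <- v[2]^2 + v[3]^2 - 4 * v[1] * v[4]
  if (scale2 <= 0) return(list(center = c(NA_real_, NA_real_), radius = Inf))
  v <- v / sqrt(scale2)
  a <- v[1]; b <- v[2]; cc <- v[3]
  if (abs(a) < 1e-12) return(list(center = c(NA_real_, NA_real_), radius = Inf))
  center <- c(-b, -cc) / (2 * a) + mu
  radius <- 1 / (2 * abs(a))
  list(center = center, radius = radius)
}

#' Local boundary curvature by windowed Pratt circle fits
#'
#' For each boundary point, its 5 neighbours per side (11 points total) are
#' fitted with the Pratt method; curvature is 1/R, signed positive where the
#' boundary bulges outward (locally convex) and negative where it is
#' concave, so protrusions carry positive curvature.
#'
#' @param pts n x 2 CCW boundary matrix (um).
#' @param half_window neighbours per side (default 5).
#' @return numeric curvature per point, um^-1 (0 for collinear windows).
#' @export
local_curvature <- function(pts, half_window = 5L) {
  n <- nrow(pts)
  normals <- outward_normals(pts)
  kappa <- numeric(n)
  for (k in seq_len(n)) {
    win <- pts[cyclic_index((k - half_window):(k + half_window), n), , drop = FALSE]
    fit <- pratt_circle_fit(win)
    if (!is.finite(fit$radius) || fit$radius <= 0) { kappa[k] <- 0; next }
    s <- sign(sum(normals[k, ] * (pts[k, ] - fit$center)))
    if (s == 0) s <- 1
    kappa[k] <- s / fit$radius
  }
  kappa
}
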