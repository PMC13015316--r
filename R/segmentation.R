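# Per-frame segmentation (global Otsu on the cell-marker channel, 3D
# connected components), centroid tracking with the minimum-displacement
# criterion, subpixel 100-point boundary extraction (level-set contour plus
# active-contour refinement), and motility classification.

#' Segment one frame by global Otsu thresholding
#'
#' Computes a single Otsu threshold over the whole 3D volume, labels the
#' connected components in 3D (26-connectivity within a plane via 8-connected
#' slices merged by overlap), and discards components below a minimum voxel
#' count.
#'
#' @param volume Z x Y x X numeric intensity array (one frame, one channel).
#' @param min_volume minimum component size in voxels.
#' @return integer Z x Y x X label array (0 = background), with the Otsu
#'   threshold attached as attribute \code{threshold}.
#' @export
segment_frame <- function(volume, min_volume = 50L) {
  if (length(dim(volume)) == 2L) volume <- array(volume, c(1L, dim(volume)))
  rng <- range(volume)
  if (diff(rng) < .Machine$double.eps)
    stop("constant intensity volume: Otsu threshold undefined")
  v <- (as.vector(volume) - rng[1]) / diff(rng)
  thr01 <- EBImage::otsu(EBImage::Image(matrix(v, ncol = 1L)),
                         range = c(0, 1), levels = 256L)
  thr <- thr01 * diff(rng) + rng[1]
  mask <- volume > thr
  labels <- label_components_3d(mask)
  if (max(labels) > 0L) {
    sizes <- tabulate(labels[labels > 0L])
    drop <- which(sizes < min_volume)
    if (length(drop)) labels[labels %in% drop] <- 0L
    labels <- relabel_consecutive(labels)
  }
  attr(labels, "threshold") <- thr
  labels
}

# 3D connected components: 2D 8-connected labelling per slice (EBImage),
# then union-find merging of labels that overlap between adjacent slices.
label_components_3d <- function(mask) {
  dz <- dim(mask)[1]
  labs <- array(0L, dim(mask))
  offset <- 0L
  for (z in seq_len(dz)) {
    sl <- EBImage::bwlabel(EBImage::Image(mask[z, , ] * 1))
    sl <- as.integer(sl)
    sl[sl > 0L] <- sl[sl > 0L] + offset
    labs[z, , ] <- sl
    offset <- max(offset, max(sl))
  }
  if (offset == 0L) return(labs)
  parent <- seq_len(offset)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (dz > 1L) for (z in seq_len(dz - 1L)) {
    a <- labs[z, , ]; b <- labs[z + 1L, , ]
    both <- a > 0L & b > 0L
    if (any(both)) {
      pr <- unique(cbind(a[both], b[both]))
      for (r in seq_len(nrow(pr))) {
        ra <- find(pr[r, 1]); rb <- find(pr[r, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  roots <- vapply(seq_len(offset), find, integer(1))
  map <- c(0L, roots)
  labs[] <- map[labs + 1L]
  relabel_consecutive(labs)
}

relabel_consecutive <- function(labels) {
  u <- sort(unique(labels[labels > 0L]))
  if (!length(u)) return(labels)
  map <- integer(max(u) + 1L)
  map[u + 1L] <- seq_along(u)
  labels[] <- ifelse(labels > 0L, map[labels + 1L], 0L)
  labels
}

# centroid table (um) for one label array
component_centroids <- function(labels, voxel_size) {
  u <- sort(unique(labels[labels > 0L]))
  if (!length(u)) return(NULL)
  dzyx <- dim(labels)
  idx <- which(labels > 0L, arr.ind = TRUE)
  lab <- labels[labels > 0L]
  vx <- voxel_size[["xy"]]; vz <- voxel_size[["z"]]
  do.call(rbind, lapply(u, function(l) {
    sel <- lab == l
    data.frame(label = l,
               x = mean(idx[sel, 3] - 0.5) * vx,
               y = mean(idx[sel, 2] - 0.5) * vx,
               z = mean(idx[sel, 1] - 0.5) * vz,
               volume = sum(sel))
  }))
}

#' Track segmented objects across frames
#'
#' Frame-to-frame assignment minimizing total centroid displacement (exact
#' enumeration for small object counts, greedy nearest-pair linking
#' otherwise), capped by a maximum linking distance. Unmatched objects start
#' or terminate tracks.
#'
#' @param labels_list list (one per frame) of 3D label arrays.
#' @param voxel_size named numeric (\code{xy}, \code{z}), um.
#' @param max_link_dist maximum allowed centroid displacement per frame, um.
#' @return data frame with cell_id, frame, label, x, y, z (um), volume.
#' @export
track_objects <- function(labels_list, voxel_size, max_link_dist = 10) {
  if (length(labels_list) < 2L) stop("need at least 2 frames to track")
  cents <- lapply(labels_list, component_centroids, voxel_size = voxel_size)
  next_id <- 1L
  rows <- list()
  prev_ids <- integer(0)
  prev <- NULL
  for (t in seq_along(cents)) {
    cur <- cents[[t]]
    if (is.null(cur)) { prev <- NULL; prev_ids <- integer(0); next }
    ids <- rep(NA_integer_, nrow(cur))
    if (!is.null(prev) && nrow(prev) > 0) {
      D <- outer(seq_len(nrow(prev)), seq_len(nrow(cur)),
                 Vectorize(function(i, j)
                   sqrt((prev$x[i] - cur$x[j])^2 + (prev$y[i] - cur$y[j])^2)))
      asn <- min_displacement_assignment(D, max_link_dist)
      for (k in seq_len(nrow(asn))) ids[asn[k, 2]] <- prev_ids[asn[k, 1]]
    }
    for (j in which(is.na(ids))) { ids[j] <- next_id; next_id <- next_id + 1L }
    rows[[t]] <- cbind(data.frame(cell_id = ids, frame = t), cur)
    prev <- cur; prev_ids <- ids
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# assignment minimizing total displacement subject to a distance cap;
# exact over permutations when feasible, greedy fallback. Returns a matrix
# with columns (row index, col index).
min_displacement_assignment <- function(D, max_dist) {
  nr <- nrow(D); nc <- ncol(D)
  k <- min(nr, nc)
  if (k == 0L) return(matrix(integer(0), 0, 2))
  small <- max(nr, nc) <= 7L
  best <- NULL
  if (small) {
    rows <- seq_len(nr); cols <- seq_len(nc)
    perms <- perms_of(if (nr <= nc) cols else rows, k)
    best_cost <- Inf
    for (p in seq_len(nrow(perms))) {
      pair <- if (nr <= nc) cbind(rows, perms[p, ]) else cbind(perms[p, ], cols)
      d <- D[pair]
      keep <- d <= max_dist
      cost <- sum(d[keep]) + sum(!keep) * max_dist * 10  # penalize dropped links
      if (cost < best_cost) { best_cost <- cost; best <- pair[keep, , drop = FALSE] }
    }
  } else {
    used_r <- logical(nr); used_c <- logical(nc); best <- NULL
    repeat {
      Dm <- D
      Dm[used_r, ] <- Inf; Dm[, used_c] <- Inf
      m <- which.min(Dm)
      if (!is.finite(Dm[m]) || Dm[m] > max_dist) break
      ij <- arrayInd(m, dim(D))
      best <- rbind(best, ij)
      used_r[ij[1]] <- TRUE; used_c[ij[2]] <- TRUE
      if (all(used_r) || all(used_c)) break
    }
    if (is.null(best)) best <- matrix(integer(0), 0, 2)
  }
  best
}

perms_of <- function(v, k) {
  if (k == 1L) return(matrix(v, ncol = 1))
  out <- NULL
  for (i in seq_along(v))
    out <- rbind(out, cbind(v[i], perms_of(v[-i], k - 1L)))
  out
}

#' Extract a 100-point subpixel boundary from one frame
#'
#' Max-projects the object's intensity along z, traces the closed contour of
#' the segmentation level set with subpixel linear interpolation, refines it
#' with a classic active contour (elasticity/rigidity-regularized snake
#' attracted to image edges), normalizes orientation to counterclockwise,
#' anchors the start index (nearest point to the previous frame's first
#' point, or the heading angle on the first frame), and resamples to exactly
#' \code{n_points} even arc-length points.
#'
#' @param volume Z x Y x X intensity array (cell-marker channel, one frame).
#' @param labels matching label array from \code{\link{segment_frame}}.
#' @param label which object to trace.
#' @param voxel_size named numeric (\code{xy}), um.
#' @param n_points boundary points (100 throughout the pipeline).
#' @param threshold segmentation threshold; defaults to the one stored on
#'   \code{labels}.
#' @param snake_iterations active-contour refinement iterations (0 skips).
#' @param alpha,beta,gamma snake elasticity, rigidity and step damping.
#' @param prev_points previous frame's boundary (for start anchoring).
#' @param heading heading angle in radians (first-frame anchoring).
#' @return list with \code{points} (n_points x 2 matrix, um, CCW),
#'   \code{border_touch} flag, and \code{area} (polygon area, um^2).
#' @export
extract_boundary <- function(volume, labels, label = 1L, voxel_size,
                             n_points = 100L, threshold = NULL,
                             snake_iterations = 15L, alpha = 0.05,
                             beta = 0.5, gamma = 2,
                             prev_points = NULL, heading = NULL) {
  if (length(dim(volume)) == 2L) volume <- array(volume, c(1L, dim(volume)))
  if (length(dim(labels)) == 2L) labels <- array(labels, c(1L, dim(labels)))
  vx <- voxel_size[["xy"]]
  thr <- threshold %||% attr(labels, "threshold")
  obj <- labels == label
  if (!any(obj)) stop("label ", label, " not present")
  proj_int <- apply(volume, c(2, 3), max)
  proj_mask <- apply(obj, c(2, 3), max)
  ny <- nrow(proj_int); nx <- ncol(proj_int)
  border_touch <- any(proj_mask[1, ]) || any(proj_mask[ny, ]) ||
    any(proj_mask[, 1]) || any(proj_mask[, nx])

  # suppress other objects so the level-set contour belongs to this one
  others <- apply(labels > 0L & !obj, c(2, 3), max) > 0
  img <- proj_int
  img[others] <- min(img)

  cy <- mean(which(proj_mask > 0, arr.ind = TRUE)[, 1] - 0.5)
  cx <- mean(which(proj_mask > 0, arr.ind = TRUE)[, 2] - 0.5)

  cl <- grDevices::contourLines(x = seq_len(ny) - 0.5, y = seq_len(nx) - 0.5,
                                z = img, levels = thr %||% stats::median(range(img)))
  pts <- NULL
  for (cc in cl) {
    cand <- cbind(cc$y, cc$x)  # (x, y) in pixel units
    closed <- sqrt(sum((cand[1, ] - cand[nrow(cand), ])^2)) < 1e-9
    if (!closed || nrow(cand) < 8) next
    cand <- cand[-nrow(cand), , drop = FALSE]
    if (points_in_polygon(cand, matrix(c(cx, cy), 1, 2))) { pts <- cand; break }
  }
  if (is.null(pts)) {
    cl <- grDevices::contourLines(x = seq_len(ny) - 0.5, y = seq_len(nx) - 0.5,
                                  z = proj_mask * 1, levels = 0.5)
    if (!length(cl)) stop("boundary extraction failed: no closed contour found")
    lens <- vapply(cl, function(cc) length(cc$x), integer(1))
    cc <- cl[[which.max(lens)]]
    pts <- cbind(cc$y, cc$x)
    if (sqrt(sum((pts[1, ] - pts[nrow(pts), ])^2)) < 1e-9)
      pts <- pts[-nrow(pts), , drop = FALSE]
  }
  pts <- ensure_ccw(pts)
  pts <- resample_closed_contour(pts, max(200L, n_points))
  if (snake_iterations > 0L)
    pts <- snake_refine(pts, img, iterations = snake_iterations,
                        alpha = alpha, beta = beta, gamma = gamma)
  pts <- ensure_ccw(pts)

  # anchor point 1
  ctr <- polygon_centroid(pts)
  start <- if (!is.null(prev_points)) {
    anchor <- prev_points[1, ] / vx
    which.min((pts[, 1] - anchor[1])^2 + (pts[, 2] - anchor[2])^2)
  } else if (!is.null(heading)) {
    ang <- atan2(pts[, 2] - ctr[2], pts[, 1] - ctr[1])
    which.min(abs(atan2(sin(ang - heading), cos(ang - heading))))
  } else 1L
  if (start > 1L) pts <- pts[c(start:nrow(pts), 1:(start - 1L)), , drop = FALSE]
  out <- resample_closed_contour(pts, n_points) * vx
  list(points = out, border_touch = border_touch, area = polygon_area(out))
}

# Classic snake: x <- (gamma*I + alpha*K2 + beta*K4)^-1 (gamma*x + f_ext),
# f_ext = gradient of the edge map |grad(G*I)| sampled bilinearly.
snake_refine <- function(pts, img, iterations = 15L, alpha = 0.05,
                         beta = 0.5, gamma = 2, sigma = 1.5) {
  n <- nrow(pts)
  sm <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = sigma))
  gy <- sm; gy[] <- 0; gx <- sm; gx[] <- 0
  gy[2:(nrow(sm) - 1), ] <- (sm[3:nrow(sm), ] - sm[1:(nrow(sm) - 2), ]) / 2
  gx[, 2:(ncol(sm) - 1)] <- (sm[, 3:ncol(sm)] - sm[, 1:(ncol(sm) - 2)]) / 2
  edge <- sqrt(gx^2 + gy^2)
  edge <- edge / max(edge, .Machine$double.eps)
  fy <- edge; fy[] <- 0; fx <- edge; fx[] <- 0
  fy[2:(nrow(edge) - 1), ] <- (edge[3:nrow(edge), ] - edge[1:(nrow(edge) - 2), ]) / 2
  fx[, 2:(ncol(edge) - 1)] <- (edge[, 3:ncol(edge)] - edge[, 1:(ncol(edge) - 2)]) / 2

  lap <- diag(2, n)
  idx <- seq_len(n)
  lap[cbind(idx, cyclic_index(idx + 1L, n))] <- -1
  lap[cbind(idx, cyclic_index(idx - 1L, n))] <- -1
  M <- gamma * diag(n) + alpha * lap + beta * (lap %*% lap)
  Minv <- solve(M)
  bilinear <- function(f, x, y) {
    x0 <- pmin(pmax(floor(x), 1), ncol(f) - 1); y0 <- pmin(pmax(floor(y), 1), nrow(f) - 1)
    dx <- pmin(pmax(x - x0, 0), 1); dy <- pmin(pmax(y - y0, 0), 1)
    f[cbind(y0, x0)] * (1 - dx) * (1 - dy) + f[cbind(y0, x0 + 1)] * dx * (1 - dy) +
      f[cbind(y0 + 1, x0)] * (1 - dx) * dy + f[cbind(y0 + 1, x0 + 1)] * dx * dy
  }
  x <- pts[, 1]; y <- pts[, 2]
  for (i in seq_len(iterations)) {
    # pixel centers sit at index - 0.5, so sample the force at index x + 0.5
    ex <- bilinear(fx, x + 0.5, y + 0.5); ey <- bilinear(fy, x + 0.5, y + 0.5)
    x <- as.vector(Minv %*% (gamma * x + ex))
    y <- as.vector(Minv %*% (gamma * y + ey))
  }
  cbind(x, y)
}

#' Classify cell motility
#'
#' Cells are motile when tracked for at least \code{min_frames} frames with
#' average speed (path length / elapsed time) at or above \code{min_speed};
#' active cells slower than that are jiggling; non-activated round objects
#' (flagged by curation input) are still.
#'
#' @param track data frame with columns frame, x, y for one cell.
#' @param frame_interval seconds.
#' @param min_frames,min_speed motile-cell thresholds (frames; um/s).
#' @param still logical curation flag marking a non-activated object.
#' @return list with \code{class} ("still", "jiggling" or "motile"),
#'   \code{avg_speed} (um/s) and \code{n_frames}.
#' @export
classify_cell_motility <- function(track, frame_interval, min_frames = 10L,
                                   min_speed = 0.1, still = FALSE) {
  n <- nrow(track)
  if (still) return(list(class = "still", avg_speed = NA_real_, n_frames = n))
  if (n < 2L) return(list(class = "jiggling", avg_speed = NA_real_, n_frames = n))
  l <- sum(sqrt(diff(track$x)^2 + diff(track$y)^2))
  speed <- l / ((n - 1) * frame_interval)
  # "no less than": a small tolerance keeps exact-threshold speeds motile
  cls <- if (n >= min_frames && speed >= min_speed - 1e-9) "motile" else "jiggling"
  list(class = cls, avg_speed = speed, n_frames = n)
}

#' Population motility fractions
#'
#' @param classes character vector of per-cell motility classes.
#' @return named numeric fractions (still, jiggling, motile).
#' @export
motility_fractions <- function(classes) {
  n <- length(classes)
  c(still = sum(classes == "still") / n,
    jiggling = sum(classes == "jiggling") / n,
    motile = sum(classes == "motile") / n)
}
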