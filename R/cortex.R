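# Cortical quantification: 100 cortical sections within a 2 um shell inside
# the boundary, per-cell intensity normalization, and the front/rear/side
# region partition driven by the migration direction.

#' Build the 100 cortical sections for one frame
#'
#' The inner cortex boundary is the 100-point boundary offset inward by
#' \code{cortex_depth} along the inward normal (clamped where the cell is
#' locally thinner than the shell, using the distance transform of the
#' projected mask). Section k is the quadrilateral between boundary points
#' k, k+1 and their inner partners; every projected cell pixel is assigned
#' to the section containing it (ties to the nearest section centre), and
#' its z-column of cell voxels contributes to that section's voxel count and
#' raw mean intensity. Pixels inside no section form the unassigned region.
#'
#' @param points 100 x 2 boundary matrix (um, CCW).
#' @param volume Z x Y x X intensity array for the cell-marker channel.
#' @param mask Z x Y x X logical array selecting this cell's voxels.
#' @param voxel_size named numeric with element \code{xy} (um/pixel).
#' @param cortex_depth shell depth, um.
#' @return object of class \code{cortical_sections}: list with \code{I_raw},
#'   \code{N} (length 100), \code{I_raw_mean}, \code{I_raw_unassigned},
#'   \code{N_unassigned}, \code{inner_points}, \code{thin_flag}.
#' @export
build_cortical_sections <- function(points, volume, mask, voxel_size,
                                    cortex_depth = 2) {
  if (length(dim(volume)) == 2L) volume <- array(volume, c(1L, dim(volume)))
  if (length(dim(mask)) == 2L) mask <- array(mask, c(1L, dim(mask)))
  n <- nrow(points)
  vx <- voxel_size[["xy"]]

  proj_mask <- apply(mask, c(2, 3), any)
  zcount <- apply(mask, c(2, 3), sum)
  isum <- apply(volume * mask, c(2, 3), sum)
  pix <- which(proj_mask, arr.ind = TRUE)           # (y, x) indices
  px <- (pix[, 2] - 0.5) * vx
  py <- (pix[, 1] - 0.5) * vx
  nvox <- zcount[pix]
  ivox <- isum[pix]
  total_vox <- sum(nvox)
  I_raw_mean <- sum(ivox) / total_vox

  # inner contour: inward offset clamped by the projected distance transform
  dist_um <- as.matrix(EBImage::distmap(EBImage::Image(proj_mask * 1))) * vx
  normals <- outward_normals(points)
  thin_flag <- FALSE
  inner <- points
  for (k in seq_len(n)) {
    target <- points[k, ] - cortex_depth * normals[k, ]
    d <- sample_image_um(dist_um, target, vx)
    if (is.na(d) || d <= 0) {
      # walk back along the ray to the deepest reachable point (medial axis)
      best <- points[k, ]; bestd <- -Inf
      for (f in seq(0.1, 1, by = 0.1)) {
        cand <- points[k, ] - f * cortex_depth * normals[k, ]
        dc <- sample_image_um(dist_um, cand, vx)
        if (!is.na(dc) && dc > bestd) { bestd <- dc; best <- cand }
      }
      inner[k, ] <- best
      thin_flag <- TRUE
    } else inner[k, ] <- target
  }

  # assign projected pixels to section quadrilaterals
  assignment <- rep(0L, nrow(pix))
  centres <- matrix(NA_real_, n, 2)
  for (k in seq_len(n)) {
    ka <- cyclic_index(k + 1L, n)
    quad <- rbind(points[k, ], points[ka, ], inner[ka, ], inner[k, ])
    centres[k, ] <- colMeans(quad)
    bb <- apply(quad, 2, range)
    cand <- which(px >= bb[1, 1] - vx & px <= bb[2, 1] + vx &
                    py >= bb[1, 2] - vx & py <= bb[2, 2] + vx)
    if (!length(cand)) next
    inq <- points_in_polygon(quad, cbind(px[cand], py[cand]))
    hit <- cand[inq]
    fresh <- hit[assignment[hit] == 0L]
    assignment[fresh] <- k
    clash <- hit[assignment[hit] != 0L & assignment[hit] != k]
    if (length(clash)) {
      d_new <- (px[clash] - centres[k, 1])^2 + (py[clash] - centres[k, 2])^2
      old <- assignment[clash]
      d_old <- (px[clash] - centres[old, 1])^2 + (py[clash] - centres[old, 2])^2
      assignment[clash[d_new < d_old]] <- k
    }
  }

  N <- numeric(n); I_raw <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    sel <- assignment == k
    N[k] <- sum(nvox[sel])
    if (N[k] > 0) I_raw[k] <- sum(ivox[sel]) / N[k]
  }
  un <- assignment == 0L
  N_un <- sum(nvox[un])
  I_un <- if (N_un > 0) sum(ivox[un]) / N_un else NA_real_

  structure(list(I_raw = I_raw, N = N, I_raw_mean = I_raw_mean,
                 I_raw_unassigned = I_un, N_unassigned = N_un,
                 inner_points = inner, thin_flag = thin_flag),
            class = "cortical_sections")
}

# bilinear sample of an image (indexed [y, x], pixel centers at
# (ix - 0.5) * vx) at a um position; NA outside.
sample_image_um <- function(img, pos, vx) {
  xf <- pos[1] / vx + 0.5; yf <- pos[2] / vx + 0.5
  x0 <- floor(xf); y0 <- floor(yf)
  if (x0 < 1 || y0 < 1 || x0 + 1 > ncol(img) || y0 + 1 > nrow(img)) return(NA_real_)
  dx <- xf - x0; dy <- yf - y0
  img[y0, x0] * (1 - dx) * (1 - dy) + img[y0, x0 + 1] * dx * (1 - dy) +
    img[y0 + 1, x0] * (1 - dx) * dy + img[y0 + 1, x0 + 1] * dx * dy
}

#' Normalize cortical intensities over a track
#'
#' The normalized level of section k at time t is
#' \code{(I_raw[k, t] - I_raw_min) / (I_raw_mean(t) - I_raw_min)}, where
#' \code{I_raw_min} is the per-cell minimum over all sections and times and
#' \code{I_raw_mean(t)} is the mean over all cell voxels at t. The smoothed
#' level at point k is the voxel-count-weighted average of sections
#' k-2 ... k+1 (cyclic); a symmetric 5-section window (k-2 ... k+2) is
#' available as a variant.
#'
#' @param I_raw T x 100 matrix of raw section means.
#' @param N T x 100 matrix of section voxel counts.
#' @param I_raw_mean length-T vector of cell-level raw means.
#' @param I_raw_unassigned optional length-T vector of unassigned-region raw
#'   means.
#' @param window \code{"printed"} (k-2 ... k+1) or \code{"symmetric"}
#'   (k-2 ... k+2).
#' @return list with \code{I} (T x 100 normalized), \code{I_smooth}
#'   (T x 100), \code{I_unassigned} (length T or NULL), \code{I_raw_min},
#'   and \code{flagged_frames} (frames where the cell is intensity-flat and
#'   the normalization is undefined).
#' @export
normalize_nmii <- function(I_raw, N, I_raw_mean, I_raw_unassigned = NULL,
                           window = c("printed", "symmetric")) {
  window <- match.arg(window)
  nt <- nrow(I_raw); np <- ncol(I_raw)
  I_raw_min <- min(I_raw, na.rm = TRUE)
  denom <- I_raw_mean - I_raw_min
  flagged <- which(denom <= .Machine$double.eps)
  denom[flagged] <- NA_real_
  I <- (I_raw - I_raw_min) / denom
  offs <- if (window == "printed") -2:1 else -2:2
  I_smooth <- matrix(NA_real_, nt, np)
  Nz <- N
  Nz[is.na(I)] <- 0
  Iz <- I
  Iz[is.na(I)] <- 0
  for (k in seq_len(np)) {
    idx <- cyclic_index(k + offs, np)
    wN <- Nz[, idx, drop = FALSE]
    sw <- rowSums(wN)
    I_smooth[, k] <- ifelse(sw > 0, rowSums(Iz[, idx, drop = FALSE] * wN) / sw, NA_real_)
  }
  I_un <- if (!is.null(I_raw_unassigned)) (I_raw_unassigned - I_raw_min) / denom else NULL
  list(I = I, I_smooth = I_smooth, I_unassigned = I_un,
       I_raw_min = I_raw_min, flagged_frames = flagged)
}

#' Partition the boundary into front, rear and side regions
#'
#' The rear is the 30-point arc centred on the boundary point whose outward
#' direction is most anti-parallel to the migration direction; the front is
#' the antipodal 30-point arc; the remaining 40 points split into two
#' 20-point sides. Widths are the spans of the front/rear points on the axis
#' perpendicular to the migration direction.
#'
#' @param points 100 x 2 boundary matrix (um, CCW).
#' @param direction migration direction, length-2 unit vector (NA if
#'   undefined; regions are then flagged undefined).
#' @return list with index vectors \code{front}, \code{rear},
#'   \code{side_left}, \code{side_right}, the per-point factor
#'   \code{region}, \code{front_width}, \code{rear_width} (um) and
#'   \code{defined}.
#' @export
assign_regions <- function(points, direction) {
  n <- nrow(points)
  stopifnot(n %% 10 == 0)
  if (any(is.na(direction))) {
    return(list(front = integer(0), rear = integer(0), side_left = integer(0),
                side_right = integer(0),
                region = factor(rep("undefined", n),
                                levels = c("front", "rear", "side", "undefined")),
                front_width = NA_real_, rear_width = NA_real_, defined = FALSE))
  }
  ctr <- polygon_centroid(points)
  outward <- sweep(points, 2, ctr)
  outward <- outward / pmax(sqrt(rowSums(outward^2)), .Machine$double.eps)
  k_rear <- which.max(-(outward %*% direction))
  arc30 <- -15L:14L
  rear <- cyclic_index(k_rear + arc30, n)
  front <- cyclic_index(k_rear + 50L + arc30, n)
  side_left <- cyclic_index(k_rear + 15L:34L, n)
  side_right <- cyclic_index(k_rear + 65L:84L, n)
  region <- factor(rep("side", n), levels = c("front", "rear", "side", "undefined"))
  region[front] <- "front"; region[rear] <- "rear"
  perp <- c(-direction[2], direction[1])
  span <- function(idx) diff(range(points[idx, , drop = FALSE] %*% perp))
  list(front = front, rear = rear, side_left = side_left,
       side_right = side_right, region = region,
       front_width = span(front), rear_width = span(rear), defined = TRUE)
}

#' Voxel-weighted normalized level of a cortical region
#'
#' \code{I'_part = sum_k I_k N_k / sum_k N_k} over the sections of the part.
#'
#' @param I length-100 normalized section levels (one frame).
#' @param N length-100 section voxel counts.
#' @param idx section indices of the part.
#' @return scalar normalized level (NA when the part has no voxels).
#' @export
region_level <- function(I, N, idx) {
  w <- N[idx]
  ok <- !is.na(I[idx]) & w > 0
  if (!any(ok)) return(NA_real_)
  sum(I[idx][ok] * w[ok]) / sum(w[ok])
}
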