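# Cell-scale motility measures: speeds, tortuosity, migration direction
# with deviation angles, and population direction autocorrelation.

#' Path-level migration metrics
#'
#' Average speed is path length / elapsed time; instantaneous speed is the
#' framewise displacement divided by the frame interval; tortuosity is path
#' length / net displacement magnitude (>= 1, undefined for closed loops).
#'
#' @param path m x 2 centroid path (um).
#' @param frame_interval seconds.
#' @return list of class \code{migration_summary} with \code{path_length},
#'   \code{elapsed}, \code{displacement}, \code{avg_speed},
#'   \code{instant_speed} (length m-1), \code{tortuosity} and
#'   \code{tortuosity_defined}.
#' @export
path_metrics <- function(path, frame_interval) {
  m <- nrow(path)
  if (m < 2L) stop("need at least 2 frames")
  steps <- sqrt(diff(path[, 1])^2 + diff(path[, 2])^2)
  l <- sum(steps)
  elapsed <- (m - 1) * frame_interval
  s <- path[m, ] - path[1, ]
  smag <- sqrt(sum(s^2))
  # closed loops: |s| below 1e-9 um is indistinguishable from zero
  defined <- smag > 1e-9
  structure(list(path_length = l, elapsed = elapsed, displacement = s,
                 avg_speed = l / elapsed, instant_speed = steps / frame_interval,
                 tortuosity = if (defined) l / smag else NA_real_,
                 tortuosity_defined = defined),
            class = "migration_summary")
}

#' Migration direction and deviation angle
#'
#' The direction at frame t is the unit displacement over the next two
#' frames (centroid(t+2) - centroid(t)), which smooths subcellular shape
#' dynamics out of the heading; it is undefined at the last two frames. The
#' deviation angle at t is the angle between n(t) and n(t+1), in [0, pi].
#'
#' @param path m x 2 centroid path (um).
#' @return list with \code{direction} (m x 2, rows of NA where undefined)
#'   and \code{deviation_angle} (length m, radians, NA where undefined).
#' @export
migration_direction <- function(path) {
  m <- nrow(path)
  dir <- matrix(NA_real_, m, 2)
  if (m >= 3L) for (t in seq_len(m - 2L)) {
    dir[t, ] <- unit_vector(path[t + 2L, ] - path[t, ])
  }
  dev <- rep(NA_real_, m)
  for (t in seq_len(max(0L, m - 3L))) {
    if (!any(is.na(dir[t, ])) && !any(is.na(dir[t + 1L, ]))) {
      d <- sum(dir[t, ] * dir[t + 1L, ])
      dev[t] <- acos(pmin(pmax(d, -1), 1))
    }
  }
  list(direction = dir, deviation_angle = dev)
}

#' Population direction autocorrelation
#'
#' Corr(dt) = <n(t) . n(t + dt)> averaged over all valid time points of all
#' cells. Corr(0) = 1 by construction.
#'
#' @param directions list of per-cell direction matrices (m_i x 2, NA rows
#'   where undefined), as produced by \code{\link{migration_direction}}.
#' @param dt_max largest offset in frames (default: half the longest track).
#' @return data frame with \code{dt} (frames), \code{corr}, \code{n_pairs};
#'   offsets with no valid pairs are absent.
#' @export
direction_autocorrelation <- function(directions, dt_max = NULL) {
  if (!length(directions)) stop("no tracks supplied")
  if (is.null(dt_max))
    dt_max <- max(1L, floor(max(vapply(directions, nrow, integer(1))) / 2))
  rows <- lapply(0:dt_max, function(dt) {
    dots <- unlist(lapply(directions, function(D) {
      m <- nrow(D)
      if (m - dt < 1L) return(numeric(0))
      a <- D[seq_len(m - dt), , drop = FALSE]
      b <- D[seq_len(m - dt) + dt, , drop = FALSE]
      v <- rowSums(a * b)
      v[!is.na(v)]
    }))
    if (!length(dots)) return(NULL)
    data.frame(dt = dt, corr = mean(dots), n_pairs = length(dots))
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}
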