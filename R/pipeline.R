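# Orchestration: run the per-cell boundary-dynamics analysis on a boundary
# series (from the generator or from segmentation), and the full
# image-to-tables pipeline on a calibrated stack.

#' Analyze a 100-point boundary series
#'
#' Computes, for one cell, the centroid path and migration directions,
#' per-point curvature, frame-to-frame point tracking with signed motion and
#' local area change, the front/rear/side region partition per frame, and
#' (when section intensities are supplied) the normalized cortical levels
#' and per-frame region levels.
#'
#' @param boundaries T x 100 x 2 array of boundary points (um, CCW).
#' @param frame_interval seconds.
#' @param I_raw,N optional T x 100 raw section intensities and voxel counts.
#' @param I_raw_mean optional length-T cell-level raw means.
#' @param I_raw_unassigned optional length-T unassigned-region raw means.
#' @param smoothing_window \code{"printed"} or \code{"symmetric"} (see
#'   \code{\link{normalize_nmii}}).
#' @return list of class \code{cell_dynamics} with elements
#'   \code{centroids}, \code{directions}, \code{kappa} (T x 100),
#'   \code{trackings}, \code{motion} ((T-1) x 100), \code{area}
#'   ((T-1) x 100), \code{area_flags}, \code{regions} (per frame),
#'   \code{norm} (see \code{\link{normalize_nmii}}; NULL without
#'   intensities), \code{frame_table} (per-frame region levels and widths),
#'   \code{frame_interval}.
#' @export
analyze_boundary_series <- function(boundaries, frame_interval,
                                    I_raw = NULL, N = NULL, I_raw_mean = NULL,
                                    I_raw_unassigned = NULL,
                                    smoothing_window = "printed") {
  nt <- dim(boundaries)[1]; np <- dim(boundaries)[2]
  centroids <- t(vapply(seq_len(nt), function(t)
    polygon_centroid(boundaries[t, , ]), numeric(2)))
  colnames(centroids) <- c("x", "y")
  dirs <- migration_direction(centroids)

  kappa <- t(vapply(seq_len(nt), function(t)
    local_curvature(boundaries[t, , ]), numeric(np)))
  trackings <- vector("list", nt - 1L)
  motion <- matrix(NA_real_, nt - 1L, np)
  area <- matrix(NA_real_, nt - 1L, np)
  area_flags <- matrix(FALSE, nt - 1L, np)
  for (t in seq_len(nt - 1L)) {
    tr <- track_boundary_points(boundaries[t, , ], boundaries[t + 1L, , ])
    trackings[[t]] <- tr
    motion[t, ] <- tr$motion
    ac <- local_area_change(boundaries[t, , ], boundaries[t + 1L, , ], tr)
    area[t, ] <- ac$area
    area_flags[t, ] <- ac$self_intersecting
  }
  regions <- lapply(seq_len(nt), function(t)
    assign_regions(boundaries[t, , ], dirs$direction[t, ]))

  norm <- NULL; frame_table <- NULL
  if (!is.null(I_raw)) {
    stopifnot(!is.null(N), !is.null(I_raw_mean))
    norm <- normalize_nmii(I_raw, N, I_raw_mean, I_raw_unassigned,
                           window = smoothing_window)
    frame_table <- do.call(rbind, lapply(seq_len(nt), function(t) {
      rg <- regions[[t]]
      if (!isTRUE(rg$defined))
        return(data.frame(frame = t, I_front = NA_real_, I_rear = NA_real_,
                          I_side = NA_real_, I_unassigned = NA_real_,
                          front_width = NA_real_, rear_width = NA_real_))
      data.frame(frame = t,
                 I_front = region_level(norm$I[t, ], N[t, ], rg$front),
                 I_rear = region_level(norm$I[t, ], N[t, ], rg$rear),
                 I_side = region_level(norm$I[t, ], N[t, ],
                                       c(rg$side_left, rg$side_right)),
                 I_unassigned = if (!is.null(norm$I_unassigned))
                   norm$I_unassigned[t] else NA_real_,
                 front_width = rg$front_width, rear_width = rg$rear_width)
    }))
  }
  structure(list(centroids = centroids, directions = dirs, kappa = kappa,
                 trackings = trackings, motion = motion, area = area,
                 area_flags = area_flags, regions = regions, norm = norm,
                 frame_table = frame_table, frame_interval = frame_interval),
            class = "cell_dynamics")
}

#' Long per-point table of a cell's boundary dynamics
#'
#' @param dyn a \code{cell_dynamics} object.
#' @param boundaries the boundary array the analysis was run on.
#' @param cell_id id column value.
#' @return data frame with cell_id, frame, k (0-based), x, y, kappa, motion,
#'   area, I, I_smooth, region.
#' @export
point_table <- function(dyn, boundaries, cell_id = 1L) {
  nt <- dim(boundaries)[1]; np <- dim(boundaries)[2]
  do.call(rbind, lapply(seq_len(nt), function(t) {
    data.frame(cell_id = cell_id, frame = t, k = seq_len(np) - 1L,
               x = boundaries[t, , 1], y = boundaries[t, , 2],
               kappa = dyn$kappa[t, ],
               motion = if (t < nt) dyn$motion[t, ] else NA_real_,
               area = if (t < nt) dyn$area[t, ] else NA_real_,
               I = if (!is.null(dyn$norm)) dyn$norm$I[t, ] else NA_real_,
               I_smooth = if (!is.null(dyn$norm)) dyn$norm$I_smooth[t, ] else NA_real_,
               region = as.character(dyn$regions[[t]]$region),
               schema_version = 1L)
  }))
}

#' Full image-to-tables pipeline for a single-cell movie
#'
#' Segments every frame of the cell-marker channel (global Otsu, 3D
#' components), tracks the objects, follows the longest track, extracts the
#' 100-point subpixel boundary per frame (anchored across frames), builds
#' the 100 cortical sections, and runs the boundary-dynamics analysis.
#'
#' @param tl a \code{\link{timelapse}}.
#' @param config configuration list (see \code{\link{default_config}}).
#' @return list with \code{dynamics} (a \code{cell_dynamics}),
#'   \code{boundaries} (T x 100 x 2), \code{sections} (per-frame
#'   \code{cortical_sections}), \code{track}, \code{motility},
#'   \code{qc} (per-frame flags).
#' @export
analyze_timelapse <- function(tl, config = default_config()) {
  stopifnot(inherits(tl, "timelapse"))
  d <- dim(tl$data)
  ch <- tl$channel_roles[["cell_marker"]]
  pd_log("info", "segmenting ", d[1], " frames")
  labels_list <- lapply(seq_len(d[1]), function(t)
    segment_frame(tl$data[t, ch, , , , drop = TRUE],
                  min_volume = config$min_component_volume))
  for (t in seq_len(d[1]))
    if (length(dim(labels_list[[t]])) == 2L)
      labels_list[[t]] <- array(labels_list[[t]], c(1L, d[4], d[5]))
  tracks <- track_objects(labels_list, tl$voxel_size)
  lens <- table(tracks$cell_id)
  cid <- as.integer(names(lens)[which.max(lens)])
  trk <- tracks[tracks$cell_id == cid, ]
  trk <- trk[order(trk$frame), ]
  motility <- classify_cell_motility(trk, tl$frame_interval,
                                     min_frames = config$min_track_frames,
                                     min_speed = config$min_speed)
  nt <- nrow(trk)
  pd_log("info", "extracting boundaries for track of ", nt, " frames")
  boundaries <- array(NA_real_, c(nt, 100L, 2L))
  qc <- data.frame(frame = trk$frame, border_touch = FALSE, thin_cortex = FALSE)
  prev_pts <- NULL
  heading0 <- {
    h <- c(trk$x[min(3L, nt)] - trk$x[1], trk$y[min(3L, nt)] - trk$y[1])
    atan2(h[2], h[1])
  }
  sections <- vector("list", nt)
  for (i in seq_len(nt)) {
    f <- trk$frame[i]
    vol <- tl$data[f, ch, , , , drop = TRUE]
    if (length(dim(vol)) == 2L) vol <- array(vol, c(1L, d[4], d[5]))
    bd <- extract_boundary(vol, labels_list[[f]], label = trk$label[i],
                           voxel_size = tl$voxel_size,
                           snake_iterations = config$snake_iterations,
                           prev_points = prev_pts,
                           heading = if (is.null(prev_pts)) heading0 else NULL)
    boundaries[i, , ] <- bd$points
    qc$border_touch[i] <- bd$border_touch
    prev_pts <- bd$points
    mask <- labels_list[[f]] == trk$label[i]
    sections[[i]] <- build_cortical_sections(bd$points, vol, mask,
                                             tl$voxel_size,
                                             cortex_depth = config$cortex_depth)
    qc$thin_cortex[i] <- sections[[i]]$thin_flag
  }
  I_raw <- do.call(rbind, lapply(sections, `[[`, "I_raw"))
  N <- do.call(rbind, lapply(sections, `[[`, "N"))
  I_mean <- vapply(sections, `[[`, numeric(1), "I_raw_mean")
  I_un <- vapply(sections, `[[`, numeric(1), "I_raw_unassigned")
  dyn <- analyze_boundary_series(boundaries, tl$frame_interval,
                                 I_raw = I_raw, N = N, I_raw_mean = I_mean,
                                 I_raw_unassigned = I_un,
                                 smoothing_window = config$smoothing_window)
  list(dynamics = dyn, boundaries = boundaries, sections = sections,
       track = trk, motility = motility, qc = qc)
}
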