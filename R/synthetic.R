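# Synthetic amoeboid-cell movie generator. A star-convex radial boundary
# model (base circle + raised-cosine protrusion bumps following scripted
# expansion/stabilization/retraction schedules) is combined with a correlated
# random walk of the centroid and a cortical intensity field with a
# rear-enriched pool and a fluctuating front pool. Everything is
# deterministic given the seed, and the generator emits boundary and
# section-intensity tables directly so downstream stages can be tested
# without rendering or segmentation.

#' Run code with a temporary RNG seed
#'
#' Saves and restores \code{.Random.seed} so library code never disturbs the
#' caller's RNG stream.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulation parameters for the synthetic cell generator
#'
#' Bundles and validates every knob of the generator. Units are physical:
#' micrometres, seconds, intensities in arbitrary units.
#'
#' @param n_frames number of frames (>= 2).
#' @param frame_interval time between frames, seconds.
#' @param voxel_size_xy pixel size in x and y, um.
#' @param voxel_size_z plane spacing in z, um.
#' @param n_z number of z planes (thin stacks; the analysis works on
#'   max-projections so depth adds no signal and 1 is the default).
#' @param cell_radius base cell radius, um. The default 6 um keeps the
#'   resting-boundary curvature (1/6 um^-1) safely below the 0.2 um^-1
#'   protrusion detection threshold.
#' @param centroid_speed centroid speed, um/s.
#' @param direction_persistence step-to-step heading correlation in [0, 1];
#'   headings follow a wrapped-normal turning walk whose expected step
#'   cosine equals this value.
#' @param protrusion_schedule data frame of scripted events with columns
#'   \code{birth_frame}, \code{angle} (radians, lab frame), \code{amplitude}
#'   (um), \code{e_duration}, \code{s_duration}, \code{r_duration} (seconds),
#'   or NULL for no protrusions.
#' @param bump_width angular half-width of the raised-cosine protrusion
#'   profile, radians. Narrow widths give high peak curvature at modest
#'   amplitude.
#' @param rear_pool_level,front_pool_level cortical pool intensities added on
#'   top of \code{background_level} at the pool centre.
#' @param front_pool_fluctuation relative temporal fluctuation amplitude of
#'   the front pool (AR(1) modulation).
#' @param pool_width angular half-width of the cortical pools, radians.
#' @param background_level intensity of the cell interior (and cortical
#'   baseline).
#' @param noise_gaussian_sd additive Gaussian read-noise sd (0 disables).
#' @param noise_poisson_gain photons per intensity unit for Poisson shot
#'   noise (0 disables).
#' @param psf_sigma Gaussian blur sigma emulating the point-spread function,
#'   um (0 disables).
#' @param cortex_depth depth of the cortical shell, um.
#' @param field_size_um field of view (x, y), um.
#' @param matrix_channel logical; add a static second channel with a fibrous
#'   texture usable as a registration reference.
#' @param seed integer RNG seed; identical seeds give bit-identical output.
#' @return object of class \code{simulation_params} (a validated list).
#' @export
simulation_params <- function(n_frames = 40L,
                              frame_interval = 6,
                              voxel_size_xy = 0.3,
                              voxel_size_z = 1,
                              n_z = 1L,
                              cell_radius = 6,
                              centroid_speed = 0.2,
                              direction_persistence = 0.8,
                              protrusion_schedule = NULL,
                              bump_width = 0.55,
                              rear_pool_level = 2,
                              front_pool_level = 1.2,
                              front_pool_fluctuation = 0.3,
                              pool_width = 1.0,
                              background_level = 1,
                              noise_gaussian_sd = 0,
                              noise_poisson_gain = 0,
                              psf_sigma = 0.3,
                              cortex_depth = 2,
                              field_size_um = c(60, 60),
                              matrix_channel = FALSE,
                              seed = 1L) {
  p <- list(n_frames = as.integer(n_frames), frame_interval = frame_interval,
            voxel_size_xy = voxel_size_xy, voxel_size_z = voxel_size_z,
            n_z = as.integer(n_z), cell_radius = cell_radius,
            centroid_speed = centroid_speed,
            direction_persistence = direction_persistence,
            protrusion_schedule = protrusion_schedule,
            bump_width = bump_width, rear_pool_level = rear_pool_level,
            front_pool_level = front_pool_level,
            front_pool_fluctuation = front_pool_fluctuation,
            pool_width = pool_width, background_level = background_level,
            noise_gaussian_sd = noise_gaussian_sd,
            noise_poisson_gain = noise_poisson_gain, psf_sigma = psf_sigma,
            cortex_depth = cortex_depth, field_size_um = field_size_um,
            matrix_channel = isTRUE(matrix_channel), seed = as.integer(seed))
  if (p$n_frames < 2L) stop("n_frames must be >= 2")
  if (p$frame_interval <= 0) stop("frame_interval must be > 0")
  if (p$voxel_size_xy <= 0 || p$voxel_size_z <= 0) stop("voxel sizes must be > 0")
  if (p$cell_radius <= 0) stop("cell_radius must be > 0")
  if (p$direction_persistence < 0 || p$direction_persistence > 1)
    stop("direction_persistence must be in [0, 1]")
  if (p$centroid_speed < 0) stop("centroid_speed must be >= 0")
  if (!is.null(p$protrusion_schedule)) {
    sch <- p$protrusion_schedule
    need <- c("birth_frame", "angle", "amplitude",
              "e_duration", "s_duration", "r_duration")
    if (!all(need %in% names(sch)))
      stop("protrusion_schedule must have columns: ", paste(need, collapse = ", "))
    if (any(sch$amplitude < 0)) stop("protrusion amplitudes must be >= 0")
    if (any(sch$amplitude > p$cell_radius))
      stop("protrusion amplitude exceeds cell_radius: boundary would lose star-convexity")
    if (any(sch$e_duration <= 0 | sch$s_duration <= 0 | sch$r_duration <= 0))
      stop("all E/S/R phase durations must be > 0")
    if (any(sch$birth_frame < 1 | sch$birth_frame > p$n_frames))
      stop("birth_frame out of range")
  }
  class(p) <- "simulation_params"
  p
}

#' Centroid walk of a synthetic cell
#'
#' The deterministic (seeded) correlated random walk used by
#' \code{\link{simulate_cell}}: headings follow a wrapped-normal turning
#' walk whose expected step cosine equals \code{direction_persistence}, and
#' the centroid advances \code{centroid_speed * frame_interval} per step
#' starting from the field centre. Exposed so schedules can be scripted
#' relative to the cell's (seed-determined) heading.
#'
#' @param params a \code{simulation_params} object.
#' @return list with \code{headings} (radians, length n_frames) and
#'   \code{path} (n_frames x 2, um).
#' @export
centroid_walk <- function(params) {
  p <- params
  nf <- p$n_frames
  with_seed(p$seed, {
    sigma <- if (p$direction_persistence >= 1) 0 else if (p$direction_persistence <= 0)
      Inf else sqrt(-2 * log(p$direction_persistence))
    turns <- if (is.finite(sigma)) stats::rnorm(nf - 1, 0, sigma) else
      stats::runif(nf - 1, -pi, pi)
    headings <- cumsum(c(stats::runif(1, 0, 2 * pi), turns))
    step <- p$centroid_speed * p$frame_interval
    origin <- p$field_size_um / 2
    dx <- step * cos(headings); dy <- step * sin(headings)
    list(headings = headings,
         path = cbind(x = origin[1] + c(0, cumsum(dx[-nf])),
                      y = origin[2] + c(0, cumsum(dy[-nf]))))
  })
}

#' Random protrusion schedule
#'
#' Draws scripted events with birth frames spread over the movie, angular
#' positions at the instantaneous leading edge (the seed-determined heading
#' at the birth frame, with a small jitter -- pseudopods form at the cell
#' front), and E/S/R phase durations in multiples of the frame interval so
#' scripted lifetimes are exactly representable in frames. Consecutive
#' events are separated in time so bumps never coexist.
#'
#' @param params a \code{simulation_params} object (schedule ignored).
#' @param n_events number of events to script.
#' @param amplitude_range range (um) for uniform amplitude draws.
#' @param e_frames,s_frames,r_frames candidate phase durations in frames.
#' @param angle_jitter uniform jitter around the heading, radians.
#' @param seed RNG seed.
#' @return data frame usable as \code{protrusion_schedule}.
#' @export
random_protrusion_schedule <- function(params, n_events = 3L,
                                       amplitude_range = c(1.8, 2.4),
                                       e_frames = 1:3, s_frames = 1:4,
                                       r_frames = 2:3, angle_jitter = 0.4,
                                       seed = 1L) {
  dt <- params$frame_interval
  walk <- centroid_walk(params)
  with_seed(seed, {
    ev <- vector("list", n_events)
    last_end <- 0L
    for (i in seq_len(n_events)) {
      ne <- sample(e_frames, 1); ns <- sample(s_frames, 1); nr <- sample(r_frames, 1)
      total <- ne + ns + nr
      birth <- last_end + sample(2:4, 1)
      if (birth + total > params$n_frames - 1L) break
      ang <- walk$headings[birth] + stats::runif(1, -angle_jitter, angle_jitter)
      ev[[i]] <- data.frame(birth_frame = birth, angle = ang %% (2 * pi),
                            amplitude = stats::runif(1, amplitude_range[1], amplitude_range[2]),
                            e_duration = ne * dt, s_duration = ns * dt,
                            r_duration = nr * dt)
      last_end <- birth + total
    }
    do.call(rbind, ev[!vapply(ev, is.null, logical(1))])
  })
}

# Raised-cosine angular kernel: 1 at 0, 0 beyond +/- width.
raised_cosine <- function(dtheta, width) {
  d <- atan2(sin(dtheta), cos(dtheta))   # wrap to (-pi, pi]
  out <- numeric(length(d))
  in_win <- abs(d) < width
  out[in_win] <- 0.5 * (1 + cos(pi * d[in_win] / width))
  out
}

# Per-frame bump amplitude from the E/S/R schedule, in frames. Amplitude
# ramps linearly over the expansion frames (reaching the scripted amplitude
# on the last expansion frame), holds through stabilization, and decays to 0
# over the retraction frames.
event_amplitude <- function(event, frame, frame_interval) {
  ne <- max(1L, round(event$e_duration / frame_interval))
  ns <- max(1L, round(event$s_duration / frame_interval))
  nr <- max(1L, round(event$r_duration / frame_interval))
  j <- frame - event$birth_frame + 1L
  if (j < 1L) return(0)
  if (j <= ne) return(event$amplitude * j / ne)
  if (j <= ne + ns) return(event$amplitude)
  if (j <= ne + ns + nr) return(event$amplitude * (1 - (j - ne - ns) / nr))
  0
}

# Cortical intensity field at boundary angles theta for one frame.
cortical_field <- function(theta, heading, front_level, params) {
  params$background_level +
    params$rear_pool_level * raised_cosine(theta - (heading + pi), params$pool_width) +
    front_level * raised_cosine(theta - heading, params$pool_width)
}

#' Simulate one synthetic amoeboid cell
#'
#' Generates the cell's boundary series (100 points per frame), the true
#' cortical section intensities (before rendering noise), the centroid path,
#' and a ground-truth record of every scripted protrusion event.
#'
#' @param params a \code{simulation_params} object.
#' @param n_points boundary points per frame.
#' @return list of class \code{synthetic_cell} with elements
#'   \code{boundaries} (n_frames x n_points x 2 array, um),
#'   \code{section_intensity} (n_frames x n_points true cortical field),
#'   \code{section_voxels} (matching voxel-count weights),
#'   \code{centroid_path} (n_frames x 2, um), \code{headings} (radians),
#'   \code{ground_truth} (list: \code{events}, \code{region_intensity},
#'   \code{speed}), and \code{params}.
#' @export
simulate_cell <- function(params, n_points = 100L) {
  stopifnot(inherits(params, "simulation_params"))
  p <- params
  nf <- p$n_frames
  walk <- centroid_walk(p)
  headings <- walk$headings
  cx <- walk$path[, 1]; cy <- walk$path[, 2]
  with_seed(p$seed + 1L, {
    # front pool AR(1) modulation
    ar <- 0.7
    z <- stats::rnorm(nf)
    u <- Reduce(function(a, b) ar * a + sqrt(1 - ar^2) * b, z, accumulate = TRUE)
    front_level <- pmax(0, p$front_pool_level * (1 + p$front_pool_fluctuation * u))

    theta <- 2 * pi * (seq_len(n_points) - 1) / n_points
    sch <- p$protrusion_schedule
    boundaries <- array(NA_real_, dim = c(nf, n_points, 2),
                        dimnames = list(NULL, NULL, c("x", "y")))
    intensity <- matrix(NA_real_, nf, n_points)
    for (t in seq_len(nf)) {
      r <- rep(p$cell_radius, n_points)
      if (!is.null(sch) && nrow(sch) > 0) {
        for (e in seq_len(nrow(sch))) {
          a <- event_amplitude(sch[e, ], t, p$frame_interval)
          if (a > 0) r <- r + a * raised_cosine(theta - sch$angle[e], p$bump_width)
        }
      }
      boundaries[t, , 1] <- cx[t] + r * cos(theta)
      boundaries[t, , 2] <- cy[t] + r * sin(theta)
      intensity[t, ] <- cortical_field(theta, headings[t], front_level[t], p)
    }

    # section voxel-count weights ~ arc length x cortex depth / pixel area
    seg_len <- matrix(NA_real_, nf, n_points)
    for (t in seq_len(nf)) {
      pts <- boundaries[t, , ]
      nxt <- pts[cyclic_index(seq_len(n_points) + 1L, n_points), ]
      seg_len[t, ] <- sqrt(rowSums((nxt - pts)^2))
    }
    voxels <- round(seg_len * p$cortex_depth / (p$voxel_size_xy^2))
    voxels[voxels < 1] <- 1

    # cell-level mean intensity: cortical sections plus the interior pool at
    # background level (voxel counts from areas)
    cell_area <- vapply(seq_len(nf), function(t) polygon_area(boundaries[t, , ]),
                        numeric(1))
    n_interior <- pmax(0, round(cell_area / p$voxel_size_xy^2) - rowSums(voxels))
    cell_mean <- (rowSums(intensity * voxels) + p$background_level * n_interior) /
      (rowSums(voxels) + n_interior)

    events <- NULL
    if (!is.null(sch) && nrow(sch) > 0) {
      ne <- pmax(1L, round(sch$e_duration / p$frame_interval))
      ns <- pmax(1L, round(sch$s_duration / p$frame_interval))
      nr <- pmax(1L, round(sch$r_duration / p$frame_interval))
      events <- data.frame(
        event_id = seq_len(nrow(sch)),
        birth_frame = sch$birth_frame, angle = sch$angle,
        amplitude = sch$amplitude,
        e_duration = sch$e_duration, s_duration = sch$s_duration,
        r_duration = sch$r_duration,
        e_frames = ne, s_frames = ns, r_frames = nr,
        lifetime_s = sch$e_duration + sch$s_duration + sch$r_duration,
        protruding_lifetime_s = sch$e_duration + sch$s_duration)
    }

    # true region means under the generator's own heading-based partition
    region_intensity <- do.call(rbind, lapply(seq_len(nf), function(t) {
      d <- atan2(sin(theta - headings[t]), cos(theta - headings[t]))
      front <- abs(d) <= (0.3 * pi)          # 30-point arc
      rear <- abs(d) >= (0.7 * pi)           # 30-point arc
      side <- !front & !rear
      data.frame(frame = t,
                 front = mean(intensity[t, front]),
                 rear = mean(intensity[t, rear]),
                 side = mean(intensity[t, side]))
    }))

    structure(list(boundaries = boundaries,
                   section_intensity = intensity,
                   section_voxels = voxels,
                   cell_mean_intensity = cell_mean,
                   interior_voxels = n_interior,
                   centroid_path = cbind(x = cx, y = cy),
                   headings = headings,
                   front_level = front_level,
                   ground_truth = list(events = events,
                                       region_intensity = region_intensity,
                                       speed = p$centroid_speed),
                   params = p),
              class = "synthetic_cell")
  })
}

#' Render a synthetic cell into a calibrated image stack
#'
#' Voxelizes the boundary series into a T x C x Z x Y x X intensity stack:
#' pixels inside the cell take the interior background level, pixels within
#' the cortical shell take the cortical field value, then a Gaussian blur of
#' \code{psf_sigma} and the configured noise are applied. Star-convexity
#' makes the inside test exact (radial comparison), so no polygon
#' rasterization error enters beyond the pixel grid itself.
#'
#' @param cell a \code{synthetic_cell} from \code{\link{simulate_cell}}.
#' @param params simulation parameters; defaults to the ones stored in
#'   \code{cell}.
#' @return a \code{\link{timelapse}} object.
#' @export
render_movie <- function(cell, params = cell$params) {
  stopifnot(inherits(cell, "synthetic_cell"))
  p <- params
  nf <- dim(cell$boundaries)[1]
  if (nf < 1L) stop("empty boundary series")
  nx <- round(p$field_size_um[1] / p$voxel_size_xy)
  ny <- round(p$field_size_um[2] / p$voxel_size_xy)
  if (min(cell$boundaries) < 0 ||
      max(cell$boundaries[, , 1]) > p$field_size_um[1] ||
      max(cell$boundaries[, , 2]) > p$field_size_um[2])
    stop("cell leaves the field of view; enlarge field_size_um or shorten the movie")
  px <- (seq_len(nx) - 0.5) * p$voxel_size_xy
  py <- (seq_len(ny) - 0.5) * p$voxel_size_xy
  nc <- if (p$matrix_channel) 2L else 1L
  data <- array(0, dim = c(nf, nc, p$n_z, ny, nx))
  theta_grid <- 2 * pi * (0:99) / 100

  matrix_tex <- NULL
  if (p$matrix_channel) {
    matrix_tex <- with_seed(p$seed + 7L, {
      tex <- matrix(stats::runif(ny * nx), ny, nx)
      as.matrix(EBImage::gblur(EBImage::Image(tex), sigma = 2)) * 4
    })
  }

  with_seed(p$seed + 13L, {
    for (t in seq_len(nf)) {
      ctr <- cell$centroid_path[t, ]
      gx <- matrix(px, ny, nx, byrow = TRUE) - ctr[1]
      gy <- matrix(py, ny, nx) - ctr[2]
      rho <- sqrt(gx^2 + gy^2)
      ang <- atan2(gy, gx)
      # radial boundary profile at each pixel's angle (interpolated)
      pts <- cell$boundaries[t, , ]
      rad <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
      rb <- stats::approx(c(theta_grid, 2 * pi), c(rad, rad[1]),
                          xout = ang %% (2 * pi))$y
      inside <- rho <= rb
      depth <- rb - rho
      img <- matrix(0, ny, nx)
      img[inside] <- p$background_level
      cort <- inside & depth <= p$cortex_depth
      fld <- cortical_field(ang[cort], cell$headings[t], cell$front_level[t], p)
      img[cort] <- fld
      if (p$psf_sigma > 0)
        img <- as.matrix(EBImage::gblur(EBImage::Image(img),
                                        sigma = p$psf_sigma / p$voxel_size_xy))
      for (z in seq_len(p$n_z)) {
        sl <- img
        if (p$noise_poisson_gain > 0)
          sl <- matrix(stats::rpois(length(sl), pmax(sl, 0) * p$noise_poisson_gain) /
                         p$noise_poisson_gain, ny, nx)
        if (p$noise_gaussian_sd > 0)
          sl <- sl + matrix(stats::rnorm(length(sl), 0, p$noise_gaussian_sd), ny, nx)
        data[t, 1, z, , ] <- sl
      }
      if (p$matrix_channel)
        for (z in seq_len(p$n_z)) data[t, 2, z, , ] <- matrix_tex
    }
  })
  timelapse(data, voxel_size = c(xy = p$voxel_size_xy, z = p$voxel_size_z),
            frame_interval = p$frame_interval,
            channel_roles = if (nc == 2L) c(cell_marker = 1L, matrix = 2L)
                            else c(cell_marker = 1L))
}

#' Simulate a population of cells and write a fixture directory
#'
#' Draws per-cell speeds (by default straddling the 0.1 um/s motility
#' threshold), simulates and renders each cell with a seed derived
#' reproducibly from the master seed, and writes movies, per-cell and
#' per-event ground-truth tables, and the echoed parameters.
#'
#' @param params template \code{simulation_params}; per-cell seed and speed
#'   are overridden.
#' @param n_cells number of cells (>= 1).
#' @param out_dir output directory (created).
#' @param seed master seed.
#' @param speed_range range of uniform per-cell speed draws, um/s.
#' @param n_events_per_cell scripted protrusion events per cell.
#' @param render logical; write rendered movies (TIFF) as well as tables.
#' @return invisibly, a list with the ground-truth tables and file paths.
#' @export
simulate_population <- function(params, n_cells, out_dir, seed = 1L,
                                speed_range = c(0.05, 0.4),
                                n_events_per_cell = 3L, render = TRUE) {
  if (n_cells < 1L) stop("n_cells must be >= 1")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  speeds <- with_seed(seed, stats::runif(n_cells, speed_range[1], speed_range[2]))
  cells <- data.frame(cell_id = seq_len(n_cells), seed = NA_integer_,
                      speed = speeds, n_frames = params$n_frames,
                      passes_motility = speeds >= 0.1 & params$n_frames >= 10)
  all_events <- list(); paths <- character(0)
  for (i in seq_len(n_cells)) {
    si <- as.integer((seed + i * 9973L) %% 2147483647L)
    cells$seed[i] <- si
    pi_ <- params
    pi_$seed <- si
    pi_$centroid_speed <- speeds[i]
    sch <- random_protrusion_schedule(pi_, n_events = n_events_per_cell, seed = si)
    pi_$protrusion_schedule <- sch
    cell <- simulate_cell(pi_)
    ev <- cell$ground_truth$events
    if (!is.null(ev)) { ev$cell_id <- i; all_events[[length(all_events) + 1L]] <- ev }
    if (render) {
      tl <- render_movie(cell)
      pth <- file.path(out_dir, sprintf("cell_%03d.tif", i))
      write_timelapse(tl, pth)
      paths <- c(paths, pth)
    }
    bt <- boundary_table(cell$boundaries, cell_id = i)
    utils::write.csv(bt, file.path(out_dir, sprintf("boundary_%03d.csv", i)),
                     row.names = FALSE)
  }
  events <- if (length(all_events)) do.call(rbind, all_events) else NULL
  utils::write.csv(cells, file.path(out_dir, "ground_truth_cells.csv"),
                   row.names = FALSE)
  if (!is.null(events))
    utils::write.csv(events, file.path(out_dir, "ground_truth_events.csv"),
                     row.names = FALSE)
  yaml::write_yaml(params_to_list(params), file.path(out_dir, "params.yaml"))
  invisible(list(cells = cells, events = events, movie_paths = paths,
                 dir = out_dir))
}

# flatten simulation_params (data-frame schedule -> list) for YAML echo
params_to_list <- function(params) {
  p <- unclass(params)
  if (!is.null(p$protrusion_schedule))
    p$protrusion_schedule <- as.list(as.data.frame(p$protrusion_schedule))
  p
}

#' Long-format boundary table
#'
#' @param boundaries n_frames x n_points x 2 array.
#' @param cell_id id column value.
#' @return data frame with cell_id, frame, point (0-based), x, y.
#' @export
boundary_table <- function(boundaries, cell_id = 1L) {
  nf <- dim(boundaries)[1]; np <- dim(boundaries)[2]
  data.frame(cell_id = cell_id,
             frame = rep(seq_len(nf), each = np),
             point = rep(seq_len(np) - 1L, nf),
             x = as.vector(t(boundaries[, , 1])),
             y = as.vector(t(boundaries[, , 2])),
             schema_version = 1L)
}
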