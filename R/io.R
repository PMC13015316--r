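# Calibrated time-lapse container and file I/O. Stacks are stored as
# T x C x Z x Y x X arrays with physical calibration (um, s). On disk a
# movie is a multi-page TIFF in T-major page order plus a YAML sidecar
# (<file>.meta.yaml) holding the axis sizes, calibration, channel roles and
# the intensity scale used for 16-bit encoding.

#' Construct a calibrated time-lapse stack
#'
#' @param data numeric array with dim T x C x Z x Y x X.
#' @param voxel_size named numeric: \code{xy} (um/pixel) and \code{z}
#'   (um/plane).
#' @param frame_interval seconds between frames.
#' @param channel_roles named integer vector mapping roles
#'   (\code{cell_marker}, optionally \code{matrix}) to channel indices.
#' @return object of class \code{timelapse}.
#' @export
timelapse <- function(data, voxel_size, frame_interval,
                      channel_roles = c(cell_marker = 1L)) {
  if (length(dim(data)) != 5L)
    stop("data must be a 5-dimensional T x C x Z x Y x X array")
  if (dim(data)[1] < 1L) stop("at least one frame required")
  if (is.null(names(voxel_size))) names(voxel_size) <- c("xy", "z")[seq_along(voxel_size)]
  if (any(voxel_size <= 0)) stop("voxel_size must be > 0")
  if (is.null(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be > 0")
  structure(list(data = data, voxel_size = voxel_size,
                 frame_interval = frame_interval,
                 channel_roles = channel_roles),
            class = "timelapse")
}

#' @export
print.timelapse <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("timelapse: %d frames, %d channel(s), %d plane(s), %d x %d px\n",
              d[1], d[2], d[3], d[5], d[4]))
  cat(sprintf("  voxel %.3g um/px, %.3g um/plane; frame interval %.3g s\n",
              x$voxel_size[["xy"]], x$voxel_size[["z"]], x$frame_interval))
  cat("  channels:", paste(names(x$channel_roles), x$channel_roles,
                           sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write a time-lapse stack to TIFF with a YAML metadata sidecar
#'
#' Pages are written in T-major order (page = ((t-1)*C + (c-1))*Z + z).
#' Intensities are scaled to [0, 1] for 16-bit storage; the scale factor is
#' recorded in the sidecar and undone on read.
#'
#' @param tl a \code{timelapse}.
#' @param path output file path (.tif).
#' @return invisibly, the path.
#' @export
write_timelapse <- function(tl, path) {
  stopifnot(inherits(tl, "timelapse"))
  d <- dim(tl$data)
  mx <- max(tl$data, 0)
  scale <- if (mx > 0) mx else 1
  pages <- vector("list", d[1] * d[2] * d[3])
  i <- 0L
  for (t in seq_len(d[1])) for (c in seq_len(d[2])) for (z in seq_len(d[3])) {
    i <- i + 1L
    pages[[i]] <- pmin(pmax(tl$data[t, c, z, , ] / scale, 0), 1)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "LZW")
  meta <- list(n_frames = d[1], n_channels = d[2], n_z = d[3],
               ny = d[4], nx = d[5],
               voxel_size_xy = as.numeric(tl$voxel_size[["xy"]]),
               voxel_size_z = as.numeric(tl$voxel_size[["z"]]),
               frame_interval = as.numeric(tl$frame_interval),
               channel_roles = as.list(tl$channel_roles),
               intensity_scale = as.numeric(scale),
               schema_version = 1L)
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Read a calibrated time-lapse stack
#'
#' Reads a multi-page TIFF written by \code{\link{write_timelapse}} (or any
#' T-major TIFF whose axis sizes are supplied). Calibration missing from the
#' sidecar must be supplied through the override arguments or an error is
#' raised.
#'
#' @param path TIFF file path.
#' @param frame_interval,voxel_size_xy,voxel_size_z metadata overrides.
#' @param n_channels,n_z axis-size overrides when no sidecar is present.
#' @param channel_roles named integer vector override.
#' @return a \code{timelapse}.
#' @export
read_timelapse <- function(path, frame_interval = NULL, voxel_size_xy = NULL,
                           voxel_size_z = NULL, n_channels = NULL, n_z = NULL,
                           channel_roles = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  meta_path <- paste0(path, ".meta.yaml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else list()
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nC <- n_channels %||% meta$n_channels %||% 1L
  nZ <- n_z %||% meta$n_z %||% 1L
  if (length(pages) %% (nC * nZ) != 0L)
    stop("ambiguous axes: ", length(pages), " pages not divisible by C*Z = ", nC * nZ)
  nT <- length(pages) %/% (nC * nZ)
  fi <- frame_interval %||% meta$frame_interval
  if (is.null(fi)) stop("frame_interval missing: not in sidecar and no override given")
  vx <- voxel_size_xy %||% meta$voxel_size_xy
  if (is.null(vx)) stop("voxel_size_xy missing: not in sidecar and no override given")
  vz <- voxel_size_z %||% meta$voxel_size_z %||% vx
  scale <- meta$intensity_scale %||% 1
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  data <- array(0, dim = c(nT, nC, nZ, ny, nx))
  i <- 0L
  for (t in seq_len(nT)) for (c in seq_len(nC)) for (z in seq_len(nZ)) {
    i <- i + 1L
    pg <- pages[[i]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1]   # drop accidental RGB
    data[t, c, z, , ] <- pg * scale
  }
  roles <- channel_roles %||%
    (if (!is.null(meta$channel_roles)) unlist(meta$channel_roles) else c(cell_marker = 1L))
  timelapse(data, voxel_size = c(xy = vx, z = vz), frame_interval = fi,
            channel_roles = roles)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Correlation-based frame registration
#'
#' Estimates one translation per frame that maximizes the cross-correlation
#' of a reference channel's max-projection with the first frame (fixed
#' reference, so drift does not accumulate), refines the integer peak to
#' subpixel precision by a parabolic fit, and applies the same shift to all
#' channels and planes.
#'
#' @param tl a \code{timelapse}.
#' @param reference_channel channel index (default: the \code{matrix} role
#'   if present, else the cell marker).
#' @param max_shift largest shift searched, pixels.
#' @param subpixel logical; parabolic peak refinement.
#' @return list with \code{shifts} (T x 2 matrix, pixels, (dy, dx)) and
#'   \code{corrected} (a \code{timelapse} with shifts undone; subpixel parts
#'   are applied by bilinear interpolation).
#' @export
register_frames <- function(tl, reference_channel = NULL, max_shift = 20L,
                            subpixel = TRUE) {
  stopifnot(inherits(tl, "timelapse"))
  d <- dim(tl$data)
  ch <- reference_channel %||%
    (if ("matrix" %in% names(tl$channel_roles)) tl$channel_roles[["matrix"]]
     else tl$channel_roles[[1]])
  proj <- function(t) apply(tl$data[t, ch, , , , drop = FALSE], 4:5, max)
  ref <- proj(1)
  if (stats::sd(ref) < .Machine$double.eps)
    stop("flat reference channel: registration undefined")
  refc <- ref - mean(ref)
  Fref <- stats::fft(refc)
  ny <- d[4]; nx <- d[5]
  shifts <- matrix(0, d[1], 2, dimnames = list(NULL, c("dy", "dx")))
  for (t in seq_len(d[1])) {
    if (t == 1L) next
    img <- proj(t)
    imgc <- img - mean(img)
    # circular cross-correlation via FFT; peak at the displacement of img
    cc <- Re(stats::fft(Fref * Conj(stats::fft(imgc)), inverse = TRUE))
    wrap <- function(i, n) ifelse(i > n / 2, i - n, i)
    idx <- arrayInd(which.max(cc), dim(cc))
    py <- idx[1]; px <- idx[2]
    dy <- wrap(py - 1L, ny); dx <- wrap(px - 1L, nx)
    if (abs(dy) > max_shift || abs(dx) > max_shift) { dy <- 0; dx <- 0 }
    if (subpixel) {
      g <- function(i, j) cc[cyclic_index(i, ny), cyclic_index(j, nx)]
      denom_y <- g(py - 1, px) - 2 * g(py, px) + g(py + 1, px)
      denom_x <- g(py, px - 1) - 2 * g(py, px) + g(py, px + 1)
      if (denom_y < 0) dy <- dy + 0.5 * (g(py - 1, px) - g(py + 1, px)) / denom_y
      if (denom_x < 0) dx <- dx + 0.5 * (g(py, px - 1) - g(py, px + 1)) / denom_x
    }
    # report the frame's content displacement relative to the reference;
    # shift_image with exactly this (dy, dx) moves the content back
    shifts[t, ] <- c(-dy, -dx)
  }
  corrected <- tl
  for (t in seq_len(d[1])) {
    if (all(shifts[t, ] == 0)) next
    for (c in seq_len(d[2])) for (z in seq_len(d[3]))
      corrected$data[t, c, z, , ] <- shift_image(tl$data[t, c, z, , ],
                                                 shifts[t, 1], shifts[t, 2])
  }
  list(shifts = shifts, corrected = corrected)
}

# Translate an image by (dy, dx) (pixels, possibly fractional) with bilinear
# interpolation; out-of-range samples take value 0.
shift_image <- function(img, dy, dx) {
  ny <- nrow(img); nx <- ncol(img)
  yy <- matrix(seq_len(ny), ny, nx) + dy
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE) + dx
  y0 <- floor(yy); x0 <- floor(xx)
  fy <- yy - y0; fx <- xx - x0
  at <- function(i, j) {
    ok <- i >= 1 & i <= ny & j >= 1 & j <= nx
    v <- numeric(length(i))
    v[ok] <- img[cbind(i[ok], j[ok])]
    v
  }
  out <- (1 - fy) * (1 - fx) * at(y0, x0) + (1 - fy) * fx * at(y0, x0 + 1) +
    fy * (1 - fx) * at(y0 + 1, x0) + fy * fx * at(y0 + 1, x0 + 1)
  matrix(out, ny, nx)
}

#' Read an analysis configuration file
#'
#' YAML key-value file; recognized keys (all optional) include
#' \code{voxel_size_xy}, \code{voxel_size_z}, \code{frame_interval},
#' \code{channel_roles}, \code{curvature_threshold}, \code{cortex_depth},
#' \code{min_track_frames}, \code{min_speed}, \code{smoothing_window},
#' \code{bootstrap_B}, \code{bootstrap_block}, \code{tthr},
#' \code{class_thresholds_s}, \code{steady_epsilon}. Unknown keys are kept
#' and passed through.
#'
#' @param path YAML file.
#' @return named list merged over the package defaults.
#' @export
read_config <- function(path) {
  cfg <- if (!is.null(path) && file.exists(path)) yaml::read_yaml(path) else list()
  utils::modifyList(default_config(), cfg)
}

#' Default analysis configuration
#' @return named list of all recognized configuration keys.
#' @export
default_config <- function() {
  list(voxel_size_xy = NULL, voxel_size_z = NULL, frame_interval = NULL,
       channel_roles = list(cell_marker = 1L),
       curvature_threshold = 0.2,       # um^-1, protrusion detector
       cortex_depth = 2,                # um
       min_track_frames = 10L,          # motile-cell filter
       min_speed = 0.1,                 # um/s, motile-cell filter
       smoothing_window = "printed",    # or "symmetric"
       bootstrap_B = 1000L,
       bootstrap_block = NULL,
       tthr = 0.5,
       high_intensity_threshold = 1.1,
       class_thresholds_s = c(stable = 6, long_life = 30),
       steady_epsilon = 0.1,            # fraction of peak rate
       snake_iterations = 15L,
       min_component_volume = 50L)
}

#' Lightweight structured logging
#'
#' Emits timestamped messages gated by \code{options(protrudyn.log_level)}
#' (\code{"debug"} < \code{"info"} < \code{"warn"}; default \code{"info"}).
#'
#' @param level one of "debug", "info", "warn".
#' @param ... message parts passed to \code{sprintf}-free paste.
#' @return invisibly, TRUE if the message was emitted.
#' @export
pd_log <- function(level = "info", ...) {
  levels <- c(debug = 1L, info = 2L, warn = 3L)
  thresh <- levels[[getOption("protrudyn.log_level", "info")]]
  if (levels[[level]] < thresh) return(invisible(FALSE))
  message(format(Sys.time(), "%H:%M:%S"), " [", level, "] ", paste0(...))
  invisible(TRUE)
}
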