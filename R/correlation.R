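# Offset correlations with bootstrap confidence intervals, zero-centered
# curvature/intensity correlations, and threshold-persistence population
# curves with per-threshold one-way ANOVA.

#' Pearson correlation at a time offset
#'
#' Correlates x(t) with y(t + dt) over the aligned overlap. A positive
#' offset of a correlation peak between front-protrusion and
#' rear-retraction series means the rear lags the front.
#'
#' @param x,y numeric series on the same time grid.
#' @param dt integer offset in frames (may be negative).
#' @return Pearson correlation (NA with a warning when fewer than 3 points
#'   overlap or either side has zero variance).
#' @export
offset_pearson <- function(x, y, dt) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (dt >= 0) { xs <- x[seq_len(n - dt)]; ys <- y[seq_len(n - dt) + dt] }
  else { xs <- x[seq_len(n + dt) - dt]; ys <- y[seq_len(n + dt)] }
  ok <- !is.na(xs) & !is.na(ys)
  xs <- xs[ok]; ys <- ys[ok]
  if (length(xs) < 3L) { warning("fewer than 3 overlapping samples"); return(NA_real_) }
  if (stats::sd(xs) < .Machine$double.eps || stats::sd(ys) < .Machine$double.eps) {
    warning("zero variance in offset overlap"); return(NA_real_)
  }
  stats::cor(xs, ys)
}

#' Offset correlation curve with bootstrap confidence intervals
#'
#' Computes the offset Pearson correlation over a grid of offsets, a
#' percentile bootstrap 95\% CI at each offset (resampling time points of
#' the aligned overlap with replacement, or stationary blocks when
#' \code{block} is set), the offset of the peak correlation, and whether the
#' peak is valid (lower CI limit above \code{valid_threshold}).
#'
#' @param x,y numeric series.
#' @param dt_grid integer offsets (frames).
#' @param B bootstrap resamples (>= 100).
#' @param seed RNG seed.
#' @param block optional stationary-bootstrap mean block length (frames).
#' @param conf CI level.
#' @param valid_threshold lower-CI validity cutoff for the peak (0.2).
#' @param ci \code{"all"} computes CIs at every offset, \code{"peak"} only
#'   at the peak offset (cheaper; other rows carry NA bounds).
#' @return object of class \code{offset_correlation}: data frame
#'   \code{curve} (dt, corr, ci_lower, ci_upper, n_overlap) plus fields
#'   \code{peak_offset} (frames), \code{peak_corr}, \code{peak_valid}.
#' @export
bootstrap_peak_offset <- function(x, y, dt_grid = -10:10, B = 1000L, seed = 1L,
                                  block = NULL, conf = 0.95,
                                  valid_threshold = 0.2, ci = c("all", "peak")) {
  ci <- match.arg(ci)
  if (B < 100L) stop("B must be >= 100")
  est <- vapply(dt_grid, function(dt) suppressWarnings(offset_pearson(x, y, dt)),
                numeric(1))
  n_over <- vapply(dt_grid, function(dt) length(x) - abs(dt), numeric(1))
  peak_i <- which.max(est)
  lower <- upper <- rep(NA_real_, length(dt_grid))
  which_ci <- if (ci == "all") seq_along(dt_grid) else peak_i
  alpha <- (1 - conf) / 2
  with_seed(seed, {
    for (i in which_ci) {
      dt <- dt_grid[i]
      n <- length(x)
      if (dt >= 0) { xs <- x[seq_len(n - dt)]; ys <- y[seq_len(n - dt) + dt] }
      else { xs <- x[seq_len(n + dt) - dt]; ys <- y[seq_len(n + dt)] }
      ok <- !is.na(xs) & !is.na(ys)
      xs <- xs[ok]; ys <- ys[ok]
      m <- length(xs)
      if (m < 3L) next
      idx <- if (is.null(block)) {
        matrix(sample.int(m, m * B, replace = TRUE), m, B)
      } else stationary_bootstrap_indices(m, B, block)
      bx <- matrix(xs[idx], m, B); by <- matrix(ys[idx], m, B)
      mx <- colMeans(bx); my <- colMeans(by)
      sxy <- colMeans(bx * by) - mx * my
      sx <- sqrt(pmax(colMeans(bx * bx) - mx^2, 0))
      sy <- sqrt(pmax(colMeans(by * by) - my^2, 0))
      r <- sxy / (sx * sy)
      r <- r[is.finite(r)]
      if (length(r) < B / 2) next
      q <- stats::quantile(r, c(alpha, 1 - alpha), names = FALSE)
      lower[i] <- q[1]; upper[i] <- q[2]
    }
  })
  curve <- data.frame(dt = dt_grid, corr = est, ci_lower = lower,
                      ci_upper = upper, n_overlap = n_over)
  structure(list(curve = curve,
                 peak_offset = dt_grid[peak_i],
                 peak_corr = est[peak_i],
                 peak_valid = isTRUE(lower[peak_i] > valid_threshold)),
            class = "offset_correlation")
}

# index matrix for the stationary block bootstrap (geometric block lengths)
stationary_bootstrap_indices <- function(m, B, mean_block) {
  p <- 1 / mean_block
  idx <- matrix(0L, m, B)
  for (b in seq_len(B)) {
    i <- 1L
    while (i <= m) {
      start <- sample.int(m, 1L)
      len <- min(m - i + 1L, stats::rgeom(1L, p) + 1L)
      idx[i:(i + len - 1L), b] <- cyclic_index(start + 0:(len - 1L), m)
      i <- i + len
    }
  }
  idx
}

#' Front/rear activity series of one cell
#'
#' Per frame, the total front protrusion activity (sum of positive local
#' area changes over the front points) and the total rear retraction
#' activity (sum of absolute negative local area changes over the rear
#' points).
#'
#' @param area (T-1) x 100 matrix of signed local area changes.
#' @param regions list (length T-1 or T) of region assignments from
#'   \code{\link{assign_regions}}.
#' @return data frame with frame, front_protrusion, rear_retraction (um^2).
#' @export
region_activity_series <- function(area, regions) {
  nt <- nrow(area)
  out <- data.frame(frame = seq_len(nt), front_protrusion = NA_real_,
                    rear_retraction = NA_real_)
  for (t in seq_len(nt)) {
    rg <- regions[[t]]
    if (!isTRUE(rg$defined)) next
    af <- area[t, rg$front]
    ar <- area[t, rg$rear]
    out$front_protrusion[t] <- sum(af[af > 0])
    out$rear_retraction[t] <- sum(abs(ar[ar < 0]))
  }
  out
}

#' Front/rear motion-direction correlation
#'
#' The motion direction of the front (rear) at frame t is the unit
#' displacement of the centroid of the polygon spanned by the front (rear)
#' boundary points. Corr(dt) is the population average of
#' n_front(t) . n_rear(t + dt); both positive and negative offsets probe
#' whether the front steers the rear.
#'
#' @param front_dirs,rear_dirs lists of per-cell direction matrices
#'   ((T-1) x 2, NA rows where motion is undefined).
#' @param dt_grid integer offsets.
#' @return data frame with dt, corr, n_pairs.
#' @export
front_rear_direction_correlation <- function(front_dirs, rear_dirs,
                                             dt_grid = -5:5) {
  stopifnot(length(front_dirs) == length(rear_dirs))
  rows <- lapply(dt_grid, function(dt) {
    dots <- unlist(mapply(function(Ff, Rr) {
      m <- min(nrow(Ff), nrow(Rr))
      ts <- seq_len(m)
      ts <- ts[ts + dt >= 1 & ts + dt <= m]
      if (!length(ts)) return(numeric(0))
      v <- rowSums(Ff[ts, , drop = FALSE] * Rr[ts + dt, , drop = FALSE])
      v[!is.na(v)]
    }, front_dirs, rear_dirs, SIMPLIFY = FALSE))
    if (!length(dots)) return(NULL)
    data.frame(dt = dt, corr = mean(dots), n_pairs = length(dots))
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Per-region sub-polygon motion directions
#'
#' @param boundaries T x 100 x 2 boundary array (um).
#' @param regions list of per-frame region assignments.
#' @param part \code{"front"} or \code{"rear"}.
#' @return (T-1) x 2 matrix of unit motion directions (NA where undefined).
#' @export
region_motion_directions <- function(boundaries, regions, part = c("front", "rear")) {
  part <- match.arg(part)
  nt <- dim(boundaries)[1]
  cents <- matrix(NA_real_, nt, 2)
  for (t in seq_len(nt)) {
    rg <- regions[[min(t, length(regions))]]
    if (!isTRUE(rg$defined)) next
    idx <- rg[[part]]
    cents[t, ] <- polygon_centroid(boundaries[t, idx, , drop = TRUE])
  }
  dirs <- matrix(NA_real_, nt - 1L, 2)
  for (t in seq_len(nt - 1L)) {
    if (any(is.na(cents[t, ])) || any(is.na(cents[t + 1L, ]))) next
    dirs[t, ] <- unit_vector(cents[t + 1L, ] - cents[t, ])
  }
  dirs
}

#' Zero-centered correlation of a signed quantity with intensity
#'
#' For x a signed quantity whose natural reference is zero (local curvature
#' or membrane motion) and y an intensity, the covariance centers only y:
#' Cov'(x, y) = <x (y - <y>)>, and
#' Corr'(x, y) = Cov' / sqrt(<x x> Cov(y, y)). A positive value means the
#' intensity is enriched where x is positive.
#'
#' @param x,y numeric vectors (pooled over points, times, cells of the
#'   region of interest).
#' @return list with \code{cov_prime}, \code{corr_prime} (NA and flagged
#'   when a denominator vanishes) and \code{defined}.
#' @export
zero_centered_correlation <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (!length(x)) return(list(cov_prime = NA_real_, corr_prime = NA_real_, defined = FALSE))
  covp <- mean(x * (y - mean(y)))
  xx <- mean(x * x)
  vy <- mean((y - mean(y))^2)
  if (xx < .Machine$double.eps || vy < .Machine$double.eps)
    return(list(cov_prime = covp, corr_prime = NA_real_, defined = FALSE))
  list(cov_prime = covp, corr_prime = covp / sqrt(xx * vy), defined = TRUE)
}

#' Time fraction above a threshold
#'
#' @param x per-frame measurement of one cell.
#' @param xthr threshold.
#' @return fraction of frames with x > xthr (NA frames dropped).
#' @export
persistence_fraction <- function(x, xthr) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  mean(x > xthr)
}

#' Population persistence curves with per-threshold ANOVA
#'
#' For every threshold, the fraction of cells per experiment whose time
#' fraction above the threshold exceeds \code{tthr}; curves are summarized
#' as mean +/- SEM over experiments, and populations are compared by a
#' one-way ANOVA at every threshold (skipped and flagged with a single
#' experiment per population).
#'
#' @param data data frame with columns \code{cell_id}, \code{experiment},
#'   \code{population}, \code{value} (one row per cell per frame).
#' @param xthr_grid thresholds.
#' @param tthr time-fraction cutoff (0.5, or 0.67 as a variant).
#' @return object of class \code{persistence_curve}: data frame with
#'   population, xthr, F_mean, F_sem, n_experiments, p_anova.
#' @export
population_persistence <- function(data, xthr_grid, tthr = 0.5) {
  need <- c("cell_id", "experiment", "population", "value")
  stopifnot(all(need %in% names(data)))
  cells <- unique(data[c("cell_id", "experiment", "population")])
  out <- list()
  for (xthr in xthr_grid) {
    f <- vapply(seq_len(nrow(cells)), function(i) {
      v <- data$value[data$cell_id == cells$cell_id[i] &
                        data$experiment == cells$experiment[i]]
      persistence_fraction(v, xthr)
    }, numeric(1))
    per_exp <- stats::aggregate(list(F = f > tthr),
                                by = cells[c("experiment", "population")],
                                FUN = mean)
    pops <- unique(per_exp$population)
    p <- NA_real_
    if (length(pops) > 1L &&
        all(table(per_exp$population) > 1L) &&
        stats::var(per_exp$F) > .Machine$double.eps) {
      p <- summary(stats::aov(F ~ population, data = per_exp))[[1]][["Pr(>F)"]][1]
    }
    for (pop in pops) {
      Fv <- per_exp$F[per_exp$population == pop]
      out[[length(out) + 1L]] <- data.frame(
        population = pop, xthr = xthr, F_mean = mean(Fv),
        F_sem = if (length(Fv) > 1L) stats::sd(Fv) / sqrt(length(Fv)) else NA_real_,
        n_experiments = length(Fv), p_anova = p)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("persistence_curve", class(res))
  res
}
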