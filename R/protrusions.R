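# High-curvature protrusion detection, tracking, lifetime classification,
# expansion/disassembly rates and cortical NMII engagement.

# maximal cyclic runs of TRUE in a logical vector; returns list of index
# vectors (a run crossing the seam is one run).
cyclic_runs <- function(flag) {
  n <- length(flag)
  if (!any(flag)) return(list())
  if (all(flag)) return(list(seq_len(n)))
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- Map(seq, starts[r$values], ends[r$values])
  # merge seam-crossing run
  if (flag[1] && flag[n] && length(runs) > 1L) {
    runs[[1]] <- c(runs[[length(runs)]], runs[[1]])
    runs[[length(runs)]] <- NULL
  }
  runs
}

#' Detect and track high-curvature protrusions of one cell
#'
#' A new protrusion is born at frame t when (i) a maximal run of
#' consecutive boundary points all with curvature above
#' \code{kappa_threshold} exists, and (ii) the run's centre (the
#' highest-curvature point with two boundary points of half-width on each
#' side, a 5-point window) does not overlap, after mapping through the
#' boundary-point tracking, any qualifying run in the previous frame. The
#' centre is then tracked forward; the protrusion keeps protruding or
#' staying while the total local area change of its centre window is
#' non-negative, and its lifetime ends at the first frame where the centre
#' rate turns negative (that frame included). Stable protrusions have
#' lifetime above \code{class_thresholds_s["stable"]} (6 s), long-life
#' protrusions above \code{class_thresholds_s["long_life"]} (30 s);
#' the rest are transient. Events still alive at the end of the movie are
#' right-censored and excluded from rate statistics.
#'
#' @param kappa T x 100 curvature matrix (um^-1).
#' @param trackings list of length T-1 of \code{\link{track_boundary_points}}
#'   results for consecutive frame pairs.
#' @param area (T-1) x 100 matrix of signed local area changes (um^2).
#' @param frame_interval seconds.
#' @param kappa_threshold detection threshold, um^-1 (0.2).
#' @param class_thresholds_s named numeric: \code{stable}, \code{long_life}.
#' @param steady_epsilon steady-stage onset: first frame whose centre rate
#'   falls below this fraction of the event's peak rate.
#' @param rate_tolerance retraction means rate < -tolerance (um^2/frame).
#' @param regions optional list of per-frame region assignments; if given,
#'   each event is labelled with its birth region.
#' @return object of class \code{protrusion_set}: list with \code{events}
#'   (data frame) and \code{traces} (list of per-event centre-index/rate
#'   data frames), plus the parameters used (recorded in
#'   \code{attr(, "config")}).
#' @export
detect_protrusions <- function(kappa, trackings, area, frame_interval,
                               kappa_threshold = 0.2,
                               class_thresholds_s = c(stable = 6, long_life = 30),
                               steady_epsilon = 0.1, rate_tolerance = 0,
                               regions = NULL) {
  nt <- nrow(kappa); np <- ncol(kappa)
  stopifnot(length(trackings) == nt - 1L, nrow(area) == nt - 1L)
  runs_by_frame <- lapply(seq_len(nt), function(t)
    cyclic_runs(kappa[t, ] > kappa_threshold))
  qual_points <- lapply(runs_by_frame, function(r) unlist(r))
  center_of_run <- function(run, t) {
    kmax <- run[which.max(kappa[t, run])]
    cyclic_index(kmax + (-2L:2L), np)
  }
  inv_corr <- lapply(trackings, function(tr) {
    inv <- integer(np); inv[tr$correspondence] <- seq_len(np); inv
  })

  events <- list(); traces <- list()
  for (t in seq_len(nt)) {
    for (run in runs_by_frame[[t]]) {
      ctr <- center_of_run(run, t)
      if (t > 1L) {
        mapped_back <- inv_corr[[t - 1L]][ctr]
        if (length(intersect(mapped_back, qual_points[[t - 1L]]))) next
      }
      ev <- track_one_protrusion(t, run, kappa, trackings, area, runs_by_frame,
                                 kappa_threshold, rate_tolerance, frame_interval,
                                 steady_epsilon)
      if (!is.null(regions)) {
        rg <- regions[[min(t, length(regions))]]
        ev$event$birth_region <- if (isTRUE(rg$defined))
          as.character(rg$region[ev$event$birth_center]) else NA_character_
      }
      events[[length(events) + 1L]] <- ev$event
      traces[[length(traces) + 1L]] <- ev$trace
    }
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(event_id = integer(0), Frame = integer(0), birth_center = integer(0),
               lifetime_frames = integer(0), lifetime_s = numeric(0),
               censored = logical(0), class = character(0),
               expansion_rate = numeric(0), disassembly_rate = numeric(0),
               steady_onset_frame = integer(0))
  if (nrow(ev)) {
    ev$event_id <- seq_len(nrow(ev))
    st <- class_thresholds_s[["stable"]]; ll <- class_thresholds_s[["long_life"]]
    ev$class <- ifelse(is.na(ev$lifetime_s), NA_character_,
                       ifelse(ev$lifetime_s > ll, "long_life",
                              ifelse(ev$lifetime_s > st, "stable", "transient")))
  }
  structure(list(events = ev, traces = traces),
            class = "protrusion_set",
            config = list(kappa_threshold = kappa_threshold,
                          class_thresholds_s = class_thresholds_s,
                          steady_epsilon = steady_epsilon,
                          rate_tolerance = rate_tolerance))
}

# follow one protrusion centre from its birth frame; returns the event row
# and the per-frame trace (centre index and centre rate).
track_one_protrusion <- function(birth, run, kappa, trackings, area,
                                 runs_by_frame, kappa_threshold,
                                 rate_tolerance, frame_interval,
                                 steady_epsilon) {
  nt <- nrow(kappa); np <- ncol(kappa)
  k_star <- integer(0)
  kmax <- run[which.max(kappa[birth, run])]
  k_star[birth] <- kmax
  t <- birth
  while (t < nt) {
    mapped <- trackings[[t]]$correspondence[k_star[t]]
    nxt_runs <- runs_by_frame[[t + 1L]]
    win <- cyclic_index(mapped + (-2L:2L), np)
    hit <- NULL
    for (r in nxt_runs) if (length(intersect(win, r))) { hit <- r; break }
    k_star[t + 1L] <- if (!is.null(hit)) hit[which.max(kappa[t + 1L, hit])] else mapped
    t <- t + 1L
  }
  frames <- birth:nt
  rate <- rep(NA_real_, length(frames))
  for (i in seq_along(frames)) {
    f <- frames[i]
    if (f <= nt - 1L)
      rate[i] <- sum(area[f, cyclic_index(k_star[f] + (-2L:2L), np)])
  }
  retract <- which(!is.na(rate) & rate < -rate_tolerance)
  censored <- !length(retract)
  if (censored) {
    lifetime_frames <- NA_integer_; lifetime_s <- NA_real_
    t_ret <- NA_integer_
  } else {
    t_ret <- frames[retract[1]]
    lifetime_frames <- t_ret - birth + 1L
    lifetime_s <- lifetime_frames * frame_interval
  }
  # expansion rate: mean centre rate before the steady stage
  expansion <- NA_real_; steady_onset <- NA_integer_; disassembly <- NA_real_
  if (!censored) {
    life_idx <- seq_len(lifetime_frames)
    lr <- rate[life_idx]
    peak <- max(lr, na.rm = TRUE)
    if (is.finite(peak) && peak > 0) {
      below <- which(!is.na(lr) & lr < steady_epsilon * peak)
      steady_i <- if (length(below)) below[1] else length(lr) + 1L
      steady_onset <- birth + steady_i - 1L
      pre <- lr[seq_len(steady_i - 1L)]
      pre <- pre[!is.na(pre) & pre > 0]
      if (length(pre)) expansion <- mean(pre) / frame_interval
    }
    post <- rate[(lifetime_frames):length(rate)]
    post <- post[!is.na(post) & post < 0]
    if (length(post)) disassembly <- mean(post) / frame_interval
  }
  list(event = data.frame(event_id = NA_integer_, Frame = birth,
                          birth_center = kmax,
                          lifetime_frames = lifetime_frames,
                          lifetime_s = lifetime_s, censored = censored,
                          class = NA_character_,
                          expansion_rate = expansion,
                          disassembly_rate = disassembly,
                          steady_onset_frame = steady_onset),
       trace = data.frame(frame = frames, center = k_star[frames], rate = rate))
}

#' Protrusion frequencies of a cell
#'
#' Number of new protrusions divided by the total migration time, overall
#' and per class.
#'
#' @param events event table from \code{\link{detect_protrusions}}.
#' @param total_time_s total migration time, seconds.
#' @return named numeric: overall, transient, stable, long_life (s^-1).
#' @export
protrusion_frequency <- function(events, total_time_s) {
  stopifnot(total_time_s > 0)
  cls <- events$class
  c(overall = nrow(events) / total_time_s,
    transient = sum(cls == "transient", na.rm = TRUE) / total_time_s,
    stable = sum(cls %in% c("stable", "long_life"), na.rm = TRUE) / total_time_s,
    long_life = sum(cls == "long_life", na.rm = TRUE) / total_time_s)
}

#' Cortical NMII engagement of one protrusion
#'
#' The protrusion NMII level at each frame of its lifetime is the
#' voxel-weighted mean normalized level over the window i = k-2 ... k+1
#' around the centre (the same window convention as the boundary smoothing);
#' the localization lifetime at a threshold is the longest consecutive run
#' of frames above it within the lifetime.
#'
#' @param trace per-event trace from \code{\link{detect_protrusions}}.
#' @param lifetime_frames event lifetime in frames (NA for censored events:
#'   the event is excluded with a flag).
#' @param I T x 100 normalized (unsmoothed) intensity matrix.
#' @param N T x 100 section voxel counts.
#' @param frame_interval seconds.
#' @param thresholds normalized-intensity threshold grid (default 1.1, the
#'   high-intensity preset).
#' @return list with \code{level} (per lifetime frame), \code{mean_level},
#'   \code{localization_lifetime_s} (named by threshold), \code{excluded}.
#' @export
protrusion_nmii <- function(trace, lifetime_frames, I, N, frame_interval,
                            thresholds = 1.1) {
  if (is.na(lifetime_frames))
    return(list(level = numeric(0), mean_level = NA_real_,
                localization_lifetime_s = stats::setNames(
                  rep(NA_real_, length(thresholds)), thresholds),
                excluded = TRUE))
  np <- ncol(I)
  frames <- trace$frame[seq_len(lifetime_frames)]
  if (any(frames > nrow(I)))
    return(list(level = numeric(0), mean_level = NA_real_,
                localization_lifetime_s = stats::setNames(
                  rep(NA_real_, length(thresholds)), thresholds),
                excluded = TRUE))
  level <- vapply(seq_along(frames), function(i) {
    f <- frames[i]; k <- trace$center[i]
    idx <- cyclic_index(k + (-2L:1L), np)
    w <- N[f, idx]
    v <- I[f, idx]
    ok <- !is.na(v) & w > 0
    if (!any(ok)) return(NA_real_)
    sum(v[ok] * w[ok]) / sum(w[ok])
  }, numeric(1))
  if (anyNA(level))
    return(list(level = level, mean_level = NA_real_,
                localization_lifetime_s = stats::setNames(
                  rep(NA_real_, length(thresholds)), thresholds),
                excluded = TRUE))
  loc <- vapply(thresholds, function(thr) {
    above <- level > thr
    if (!any(above)) return(0)
    r <- rle(above)
    max(r$lengths[r$values]) * frame_interval
  }, numeric(1))
  list(level = level, mean_level = mean(level),
       localization_lifetime_s = stats::setNames(loc, thresholds),
       excluded = FALSE)
}
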