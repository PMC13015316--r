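# Globally aligned protrusion windows, directional parameters, PCA-based
# composite directionality index (CDI) with median-split states, and
# first-order temporal organization of protrusion state sequences.

#' Globally aligned protrusion window
#'
#' The window is defined in the cell's global frame coordinates:
#' \code{start_index = Frame - 1} (zero-based), \code{total_frames =
#' round(lifetime / frame_interval)}, i.e. the half-open interval
#' [start_index, start_index + total_frames). Expansion, stabilization and
#' retraction durations are converted to frame counts and applied
#' sequentially within the window; windows reaching past the end of the
#' track are truncated and flagged.
#'
#' @param Frame 1-based global onset frame of the protrusion.
#' @param lifetime_s protrusion lifetime, seconds.
#' @param e_s,s_s,r_s phase durations, seconds.
#' @param frame_interval seconds per frame.
#' @param track_length frames in the cell's track.
#' @return list with \code{start_index} (0-based), \code{total_frames},
#'   \code{phase_frames} (named E, S, R), \code{frames} (1-based frame
#'   indices inside the window), \code{truncated},
#'   \code{phase_sum_mismatch}.
#' @export
protrusion_window <- function(Frame, lifetime_s, e_s, s_s, r_s,
                              frame_interval, track_length) {
  if (Frame < 1L) stop("Frame must be >= 1")
  start_index <- Frame - 1L
  total_frames <- as.integer(round(lifetime_s / frame_interval))
  ph <- c(E = as.integer(round(e_s / frame_interval)),
          S = as.integer(round(s_s / frame_interval)),
          R = as.integer(round(r_s / frame_interval)))
  mismatch <- sum(ph) != total_frames
  over <- sum(ph) - total_frames
  for (phase in c("R", "S", "E")) {        # trim from the tail phases first
    if (over <= 0L) break
    red <- min(ph[[phase]], over)
    ph[phase] <- ph[[phase]] - red
    over <- over - red
  }
  end_excl <- start_index + total_frames          # 0-based exclusive end
  truncated <- end_excl > track_length
  frames <- seq.int(start_index + 1L, min(end_excl, track_length))
  list(start_index = start_index, total_frames = total_frames,
       phase_frames = ph, frames = frames,
       truncated = truncated, phase_sum_mismatch = mismatch)
}

#' Estimate E/S/R phase durations from a protrusion rate profile
#'
#' The phase boundaries are read off the centre-rate trace: expansion while
#' the rate stays above \code{epsilon} times the peak rate, stabilization
#' for the remaining lifetime frames, retraction for the trailing
#' negative-rate frames. This is a rate-profile surrogate for phase
#' durations, recorded as such.
#'
#' @param trace per-event trace from \code{\link{detect_protrusions}}.
#' @param lifetime_frames event lifetime in frames.
#' @param frame_interval seconds.
#' @param epsilon fraction of peak rate separating expansion from
#'   stabilization.
#' @return named numeric: e_s, s_s, r_s (seconds).
#' @export
estimate_phase_durations <- function(trace, lifetime_frames, frame_interval,
                                     epsilon = 0.1) {
  if (is.na(lifetime_frames))
    return(c(e_s = NA_real_, s_s = NA_real_, r_s = NA_real_))
  lr <- trace$rate[seq_len(lifetime_frames)]
  peak <- max(lr, na.rm = TRUE)
  ne <- if (is.finite(peak) && peak > 0) sum(!is.na(lr) & lr > epsilon * peak) else 0L
  ns <- lifetime_frames - ne
  post <- trace$rate[-seq_len(lifetime_frames)]
  nr <- 0L
  for (v in post) { if (!is.na(v) && v < 0) nr <- nr + 1L else break }
  c(e_s = ne * frame_interval, s_s = ns * frame_interval,
    r_s = nr * frame_interval)
}

#' Directional parameters of a protrusion-window subpath
#'
#' Standard motility descriptors of the centroid subpath: net displacement
#' (ND, um), total path length (TPL, um), straightness (STA = ND/TPL),
#' persistence ratio (PR, mean cosine of turning angles), angular
#' variability (ANGVAR, circular variance of turning angles), turning index
#' (TI, mean |turning angle| / pi), turning probabilities TP15 ... TP85
#' (fraction of turning angles exceeding 15 to 85 degrees in 10-degree
#' steps), and average speed (TPL / window duration, um/s).
#'
#' @param path m x 2 centroid subpath (um), m >= 3.
#' @param frame_interval seconds.
#' @return named numeric vector of the 15 parameters.
#' @export
directional_parameters <- function(path, frame_interval) {
  m <- nrow(path)
  if (m < 3L) stop("subpath needs at least 3 positions (2 steps)")
  steps <- diff(path)
  lens <- sqrt(rowSums(steps^2))
  nd <- sqrt(sum((path[m, ] - path[1, ])^2))
  tpl <- sum(lens)
  sta <- if (tpl > .Machine$double.eps) nd / tpl else NA_real_
  # signed turning angles between consecutive non-degenerate steps
  ok <- lens > .Machine$double.eps
  ang <- atan2(steps[, 2], steps[, 1])
  turns <- c()
  for (i in seq_len(nrow(steps) - 1L)) {
    if (ok[i] && ok[i + 1L]) {
      d <- ang[i + 1L] - ang[i]
      turns <- c(turns, atan2(sin(d), cos(d)))
    }
  }
  if (!length(turns)) {
    pr <- angvar <- ti <- NA_real_
    tps <- rep(NA_real_, 8)
  } else {
    pr <- mean(cos(turns))
    angvar <- 1 - sqrt(mean(cos(turns))^2 + mean(sin(turns))^2)
    ti <- mean(abs(turns)) / pi
    tps <- vapply(seq(15, 85, by = 10) * pi / 180,
                  function(th) mean(abs(turns) > th), numeric(1))
  }
  out <- c(ND = nd, TPL = tpl, STA = sta, PR = pr, ANGVAR = angvar, TI = ti,
           tps, avg_speed = tpl / ((m - 1) * frame_interval))
  names(out)[7:14] <- paste0("TP", seq(15, 85, by = 10))
  out
}

#' PCA and composite directionality index
#'
#' Columns are z-scored ((x - mean) / sd; constant columns dropped with a
#' warning), principal components are computed by singular value
#' decomposition, and the sign of PC1 is fixed so that its correlation with
#' net displacement (the most direct proxy of directional migration) is
#' non-negative. The CDI of each row is the mean of its z-scores;
#' protrusions (or cells) are stratified into high- and low-directionality
#' states by the median CDI, with ties and exact-median rows assigned to
#' low.
#'
#' @param X numeric matrix or data frame of directional parameters (rows =
#'   protrusions or cells).
#' @param anchor column name used to fix the PC1 sign (default
#'   \code{"ND"}; falls back to the first column).
#' @return object of class \code{directionality_table}: list with \code{z},
#'   \code{loadings}, \code{scores}, \code{var_explained}, \code{cdi},
#'   \code{state} (factor high/low), \code{dropped_columns}.
#' @export
pca_cdi <- function(X, anchor = "ND") {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 rows")
  if (anyNA(X)) stop("parameter matrix contains NA; exclude flagged rows first")
  sds <- apply(X, 2, stats::sd)
  # relative guard: a column whose spread is at rounding level of its mean
  # is constant for all practical purposes and would amplify noise into z
  const <- sds <= 1e-10 * pmax(1, abs(colMeans(X)))
  dropped <- colnames(X)[const]
  if (length(dropped)) {
    warning("dropping constant column(s): ", paste(dropped, collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  z <- scale(X)
  attr(z, "scaled:center") <- NULL; attr(z, "scaled:scale") <- NULL
  sv <- svd(z)
  scores <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  loadings <- sv$v
  rownames(loadings) <- colnames(X)
  anchor_col <- if (anchor %in% colnames(X)) X[, anchor] else X[, 1]
  if (stats::sd(scores[, 1]) > 0 &&
      stats::cor(scores[, 1], anchor_col) < 0) {
    scores[, 1] <- -scores[, 1]
    loadings[, 1] <- -loadings[, 1]
  }
  var_explained <- sv$d^2 / sum(sv$d^2)
  cdi <- rowMeans(z)
  med <- stats::median(cdi)
  state <- factor(ifelse(cdi > med, "high", "low"), levels = c("high", "low"))
  structure(list(z = z, loadings = loadings, scores = scores,
                 var_explained = var_explained, cdi = cdi, state = state,
                 dropped_columns = dropped),
            class = "directionality_table")
}

#' Protrusion-state transitions and run lengths
#'
#' Protrusions are ordered by onset frame within each cell; transition
#' probabilities P(A -> B) = transitions A -> B / all transitions out of A
#' are pooled over cells, and run lengths (consecutive same-state
#' protrusions) are collected per state.
#'
#' @param states data frame with columns \code{cell_id}, \code{onset}
#'   (global frame), \code{state} (factor or character, "high"/"low").
#' @return object of class \code{transition_stats}: list with
#'   \code{transition_counts} (2 x 2), \code{transition_prob} (rows sum to 1
#'   where defined), \code{runs} (data frame cell_id, state, length),
#'   \code{mean_run_length} (named numeric).
#' @export
transitions_and_runs <- function(states) {
  stopifnot(all(c("cell_id", "onset", "state") %in% names(states)))
  lv <- c("high", "low")
  counts <- matrix(0L, 2, 2, dimnames = list(from = lv, to = lv))
  runs <- list()
  for (cid in unique(states$cell_id)) {
    s <- states[states$cell_id == cid, ]
    s <- s[order(s$onset), ]
    seqs <- as.character(s$state)
    if (length(seqs) >= 2L)
      for (i in seq_len(length(seqs) - 1L))
        counts[seqs[i], seqs[i + 1L]] <- counts[seqs[i], seqs[i + 1L]] + 1L
    r <- rle(seqs)
    runs[[length(runs) + 1L]] <- data.frame(cell_id = cid, state = r$values,
                                            length = r$lengths)
  }
  runs <- do.call(rbind, runs)
  prob <- counts / pmax(rowSums(counts), 1L)
  prob[rowSums(counts) == 0L, ] <- NA_real_
  mrl <- vapply(lv, function(st) {
    ln <- runs$length[runs$state == st]
    if (length(ln)) mean(ln) else NA_real_
  }, numeric(1))
  structure(list(transition_counts = counts, transition_prob = prob,
                 runs = runs, mean_run_length = mrl),
            class = "transition_stats")
}
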