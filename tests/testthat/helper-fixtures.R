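# Fixtures are built in code; no binary data ships with the package.

# n points of an exact circle, CCW, starting at angle 0
make_circle <- function(n = 100L, r = 6, ctr = c(0, 0)) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(ctr[1] + r * cos(th), ctr[2] + r * sin(th))
}

# smooth star-convex random shape r(theta) = r0 + sum_m a_m cos(m theta + phi_m)
make_smooth_shape <- function(n = 100L, r0 = 6, n_modes = 4, amp = 0.4,
                              ctr = c(0, 0), seed = 1) {
  set.seed(seed)
  th <- 2 * pi * (seq_len(n) - 1) / n
  r <- rep(r0, n)
  for (m in seq_len(n_modes))
    r <- r + stats::runif(1, 0, amp) * cos(m * th + stats::runif(1, 0, 2 * pi))
  cbind(ctr[1] + r * cos(th), ctr[2] + r * sin(th))
}

# geometric (orthogonal least-squares) circle fit: independent oracle for the
# Pratt fit. Optimizes the centre; the optimal radius for a fixed centre is
# the mean distance.
geometric_circle_fit <- function(pts) {
  obj <- function(c0) {
    d <- sqrt((pts[, 1] - c0[1])^2 + (pts[, 2] - c0[2])^2)
    sum((d - mean(d))^2)
  }
  init <- protrudyn::pratt_circle_fit(pts)
  start <- if (all(is.finite(init$center))) init$center else colMeans(pts)
  opt <- stats::optim(start, obj, method = "BFGS",
                      control = list(reltol = 1e-15, maxit = 500))
  d <- sqrt((pts[, 1] - opt$par[1])^2 + (pts[, 2] - opt$par[2])^2)
  list(center = opt$par, radius = mean(d))
}

# default-conditions synthetic cell with scripted front protrusions
make_protrusive_cell <- function(seed, n_frames = 30L, n_events = 3L) {
  p <- simulation_params(n_frames = n_frames, centroid_speed = 0.1,
                         direction_persistence = 0.95, seed = seed)
  p$protrusion_schedule <- random_protrusion_schedule(p, n_events = n_events,
                                                      seed = seed + 100L)
  list(params = p, cell = simulate_cell(p))
}

# match detected protrusion events to scripted ground truth by birth frame
# (+/- 1 frame); returns per-truth-event detection flag and lifetime error (s)
match_events <- function(detected, truth) {
  t(vapply(seq_len(nrow(truth)), function(i) {
    cand <- detected[!is.na(detected$Frame) &
                       abs(detected$Frame - truth$birth_frame[i]) <= 1, , drop = FALSE]
    if (!nrow(cand)) return(c(found = 0, err = NA_real_))
    err <- suppressWarnings(min(abs(cand$lifetime_s -
                                      truth$protruding_lifetime_s[i]), na.rm = TRUE))
    c(found = 1, err = err)
  }, numeric(2)))
}
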