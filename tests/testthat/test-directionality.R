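test_that("protrusion windows follow the global-frame slicing rules", {
  w <- protrusion_window(Frame = 5, lifetime_s = 54, e_s = 12, s_s = 18,
                        r_s = 24, frame_interval = 6, track_length = 40)
  expect_equal(w$start_index, 4)                 # Frame - 1, zero-based
  expect_equal(w$total_frames, 9)                # round(54 / 6)
  expect_equal(unname(w$phase_frames), c(2, 3, 4))
  expect_equal(w$frames, 5:13)                   # [start, start + total) 1-based
  expect_false(w$truncated)
  expect_false(w$phase_sum_mismatch)
  # windows past the track end are truncated and flagged
  w2 <- protrusion_window(5, 54, 12, 18, 24, 6, track_length = 10)
  expect_true(w2$truncated)
  expect_equal(max(w2$frames), 10)
  # rounding mismatches between lifetime and phase sums are flagged and the
  # overshoot trimmed from the retraction phase
  w3 <- protrusion_window(1, 18, 10, 10, 10, 6, 40)   # phases round to 2+2+2 > 3
  expect_true(w3$phase_sum_mismatch)
  expect_lte(sum(w3$phase_frames), w3$total_frames)
  expect_error(protrusion_window(0, 12, 6, 6, 6, 6, 40), "Frame")
})

test_that("directional parameters hit their limit cases", {
  straight <- cbind(0:5, 0)
  dp <- directional_parameters(straight, 6)
  expect_equal(unname(dp["STA"]), 1)
  expect_equal(unname(dp["PR"]), 1)
  expect_equal(unname(dp["ANGVAR"]), 0)
  expect_equal(unname(dp["TI"]), 0)
  expect_equal(unname(dp[paste0("TP", seq(15, 85, 10))]), rep(0, 8))
  expect_equal(unname(dp["avg_speed"]), 5 / 30)
  # alternating +/-90 degree zigzag
  zig <- cbind(c(0, 1, 1, 2, 2, 3), c(0, 0, 1, 1, 2, 2))
  dz <- directional_parameters(zig, 6)
  expect_equal(unname(dz["TP85"]), 1)
  expect_lt(unname(dz["STA"]), 1)
  expect_equal(unname(dz["TI"]), 0.5)
  expect_error(directional_parameters(straight[1:2, ], 6), "at least 3")
})

test_that("directional parameters match a brute-force recomputation", {
  set.seed(14)
  for (i in 1:20) {
    path <- apply(matrix(rnorm(20), 10, 2), 2, cumsum)
    dp <- directional_parameters(path, 6)
    steps <- diff(path)
    nd <- sqrt(sum((path[10, ] - path[1, ])^2))
    tpl <- sum(sqrt(rowSums(steps^2)))
    ang <- atan2(steps[, 2], steps[, 1])
    turns <- atan2(sin(diff(ang)), cos(diff(ang)))
    expect_equal(unname(dp["ND"]), nd, tolerance = 1e-12)
    expect_equal(unname(dp["STA"]), nd / tpl, tolerance = 1e-12)
    expect_equal(unname(dp["PR"]), mean(cos(turns)), tolerance = 1e-12)
    expect_equal(unname(dp["TP45"]), mean(abs(turns) > 45 * pi / 180),
                 tolerance = 1e-12)
  }
})

test_that("z-scoring, CDI and the median split follow their contracts", {
  set.seed(21)
  X <- matrix(rnorm(60, 10, 3), 12, 5,
              dimnames = list(NULL, c("ND", "TPL", "STA", "PR", "TI")))
  pc <- pca_cdi(X)
  expect_lt(max(abs(colMeans(pc$z))), 1e-10)
  expect_lt(max(abs(apply(pc$z, 2, sd) - 1)), 1e-10)
  # loadings orthonormal
  expect_equal(crossprod(pc$loadings), diag(5), tolerance = 1e-10)
  # PC1 correlates non-negatively with ND
  expect_gte(cor(pc$scores[, 1], X[, "ND"]), 0)
  # median split sizes: floor/ceiling halves, exact-median row to low
  expect_equal(sort(as.vector(table(pc$state))), c(6, 6))
  odd <- pca_cdi(X[1:11, ])
  expect_equal(unname(table(odd$state)["low"]), 6L)   # ceiling(11/2) to low
  # a row at every column mean has CDI 0
  X2 <- rbind(X, colMeans(X))
  pc2 <- pca_cdi(X2)
  expect_equal(unname(pc2$cdi[13]), 0, tolerance = 1e-10)
  # rescaling a raw column leaves z, CDI and scores (up to sign) unchanged
  X3 <- X; X3[, 2] <- X3[, 2] * 10
  pc3 <- pca_cdi(X3)
  expect_equal(pc3$z, pc$z, tolerance = 1e-10)
  expect_equal(pc3$cdi, pc$cdi, tolerance = 1e-10)
  expect_equal(abs(pc3$scores), abs(pc$scores), tolerance = 1e-8)
  # constant columns are dropped with a warning
  X4 <- cbind(X, CONST = 5)
  expect_warning(pc4 <- pca_cdi(X4), "constant")
  expect_equal(pc4$dropped_columns, "CONST")
})

test_that("a rank-1 parameter matrix is fully captured by PC1", {
  set.seed(30)
  factor_scores <- rnorm(40)
  load <- c(1, -0.5, 2, 0.8)
  X <- outer(factor_scores, load) +
    matrix(rnorm(160, 0, 1e-8), 40, 4)
  colnames(X) <- c("ND", "a", "b", "c")
  pc <- pca_cdi(X)
  expect_gt(pc$var_explained[1], 0.999)
  expect_gt(abs(cor(pc$scores[, 1], factor_scores)), 0.999)
})

test_that("median CDI separates persistent from turning subpath regimes", {
  paths <- function(rho, speed, seed) {
    p <- simulation_params(n_frames = 10, direction_persistence = rho,
                           centroid_speed = speed, seed = seed,
                           field_size_um = c(500, 500))
    centroid_walk(p)$path
  }
  X <- do.call(rbind, lapply(1:200, function(i) {
    rho <- if (i <= 100) 0.95 else 0.3
    directional_parameters(paths(rho, 0.1 + 0.3 * ((i * 3) %% 10) / 10,
                                 i + 500), 6)
  }))
  pc <- pca_cdi(X)
  truth <- rep(c("high", "low"), each = 100)
  agree <- mean(as.character(pc$state) == truth)
  expect_gte(max(agree, 1 - agree), 0.90)
})

test_that("transition probabilities and run lengths match hand enumeration", {
  ts <- transitions_and_runs(data.frame(cell_id = 1, onset = 1:4,
                                        state = c("high", "high", "low", "high")))
  expect_equal(ts$transition_prob["high", "high"], 0.5)
  expect_equal(ts$transition_prob["high", "low"], 0.5)
  expect_equal(ts$transition_prob["low", "high"], 1)
  expect_equal(unname(ts$mean_run_length["high"]), 1.5)  # runs {2, 1}
  expect_equal(unname(ts$mean_run_length["low"]), 1)
  # rows sum to 1 where transitions exist; run lengths conserve counts
  expect_equal(rowSums(ts$transition_counts) / rowSums(ts$transition_counts),
               c(high = 1, low = 1))
  expect_equal(sum(ts$runs$length), 4)
  # all-high sequence of length m
  m <- 7
  ts2 <- transitions_and_runs(data.frame(cell_id = 1, onset = 1:m,
                                         state = rep("high", m)))
  expect_equal(ts2$transition_prob["high", "high"], 1)
  expect_true(all(is.na(ts2$transition_prob["low", ])))
  expect_equal(ts2$runs$length, m)
  # single-protrusion cells contribute runs but no transitions
  ts3 <- transitions_and_runs(data.frame(cell_id = c(1, 2), onset = c(1, 1),
                                         state = c("high", "low")))
  expect_equal(sum(ts3$transition_counts), 0L)
  expect_equal(nrow(ts3$runs), 2L)
})

test_that("phase durations are recoverable from the rate profile", {
  sch <- data.frame(birth_frame = 3, angle = 0, amplitude = 2,
                    e_duration = 12, s_duration = 18, r_duration = 12)
  p <- simulation_params(n_frames = 14, centroid_speed = 0, seed = 5,
                         protrusion_schedule = sch)
  cell <- simulate_cell(p)
  dyn <- analyze_boundary_series(cell$boundaries, p$frame_interval)
  ps <- detect_protrusions(dyn$kappa, dyn$trackings, dyn$area, p$frame_interval)
  ph <- estimate_phase_durations(ps$traces[[1]], ps$events$lifetime_frames[1],
                                 p$frame_interval)
  expect_equal(unname(ph["e_s"] + ph["s_s"]), ps$events$lifetime_s[1])
  expect_gt(ph[["r_s"]], 0)
})
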