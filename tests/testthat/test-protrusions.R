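dyn_of <- function(cell, params) {
  analyze_boundary_series(cell$boundaries, params$frame_interval,
                          I_raw = cell$section_intensity,
                          N = cell$section_voxels,
                          I_raw_mean = cell$cell_mean_intensity)
}

test_that("a scripted bump is born exactly once, at its birth frame", {
  sch <- data.frame(birth_frame = 4, angle = 0, amplitude = 2,
                    e_duration = 12, s_duration = 18, r_duration = 12)
  p <- simulation_params(n_frames = 14, centroid_speed = 0, seed = 5,
                         protrusion_schedule = sch)
  cell <- simulate_cell(p)
  dyn <- dyn_of(cell, p)
  ps <- detect_protrusions(dyn$kappa, dyn$trackings, dyn$area, p$frame_interval)
  expect_equal(nrow(ps$events), 1L)             # persistent bump: one birth
  expect_equal(ps$events$Frame, 4L)
  expect_gt(max(dyn$kappa[4, ]), 0.3)
})

test_that("a quiescent boundary yields zero events", {
  p <- simulation_params(n_frames = 8, protrusion_schedule = NULL, seed = 2)
  cell <- simulate_cell(p)
  dyn <- dyn_of(cell, p)
  ps <- detect_protrusions(dyn$kappa, dyn$trackings, dyn$area, p$frame_interval)
  expect_equal(nrow(ps$events), 0L)
})

test_that("lifetimes end at retraction onset and classes follow the 6/30 s cuts", {
  mk <- function(e, s, r) {
    sch <- data.frame(birth_frame = 3, angle = 0, amplitude = 2.2,
                      e_duration = e, s_duration = s, r_duration = r)
    p <- simulation_params(n_frames = 3 + (e + s + r) / 6 + 4,
                           centroid_speed = 0, seed = 7,
                           protrusion_schedule = sch)
    cell <- simulate_cell(p)
    dyn <- dyn_of(cell, p)
    detect_protrusions(dyn$kappa, dyn$trackings, dyn$area, p$frame_interval)$events
  }
  # E+S = 24 s before retraction -> lifetime 24 s, stable
  ev <- mk(12, 12, 12)
  expect_equal(ev$lifetime_s, 24)
  expect_equal(ev$class, "stable")
  # E+S = 36 s -> long-life (> 30 s)
  ev2 <- mk(12, 24, 12)
  expect_equal(ev2$lifetime_s, 36)
  expect_equal(ev2$class, "long_life")
  # shortest schedulable protruding phase (1+1 frames) -> 12 s, still stable;
  # transient (< 6 s) events arise only from immediately-retracting regions
  ev3 <- mk(6, 6, 12)
  expect_equal(ev3$lifetime_s, 12)
  expect_equal(ev3$class, "stable")
})

test_that("class labels partition events and long-life implies stable", {
  fx <- make_protrusive_cell(seed = 61, n_frames = 36, n_events = 4)
  dyn <- dyn_of(fx$cell, fx$params)
  ps <- detect_protrusions(dyn$kappa, dyn$trackings, dyn$area,
                           fx$params$frame_interval)
  done <- ps$events[!ps$events$censored, ]
  expect_true(all(done$class %in% c("transient", "stable", "long_life")))
  expect_true(all(done$lifetime_s[done$class == "long_life"] > 30))
  expect_true(all(done$lifetime_s[done$class == "transient"] <= 6))
})

test_that("expansion and disassembly rates reflect the scripted symmetry", {
  sch <- data.frame(birth_frame = 3, angle = 0, amplitude = 2,
                    e_duration = 18, s_duration = 12, r_duration = 18)
  p <- simulation_params(n_frames = 14, centroid_speed = 0, seed = 9,
                         protrusion_schedule = sch)
  cell <- simulate_cell(p)
  dyn <- dyn_of(cell, p)
  ps <- detect_protrusions(dyn$kappa, dyn$trackings, dyn$area, p$frame_interval)
  ev <- ps$events
  expect_gt(ev$expansion_rate, 0)
  expect_lt(ev$disassembly_rate, 0)
  # symmetric E and R schedules: magnitudes agree within 30%
  expect_lt(abs(ev$expansion_rate + ev$disassembly_rate) /
              ev$expansion_rate, 0.3)
  # rate trace consistency: expansion = mean positive centre rate before the
  # steady stage, per the recorded config
  tr <- ps$traces[[1]]
  cfg <- attr(ps, "config")
  life <- ev$lifetime_frames
  lr <- tr$rate[seq_len(life)]
  peak <- max(lr, na.rm = TRUE)
  steady <- which(lr < cfg$steady_epsilon * peak)[1]
  pre <- lr[seq_len(steady - 1L)]
  expect_equal(ev$expansion_rate,
               mean(pre[pre > 0]) / p$frame_interval, tolerance = 1e-9)
})

test_that("protrusion frequency is the count over the migration time", {
  ev <- data.frame(class = c("stable", "stable", "transient", "long_life",
                             "stable"))
  fr <- protrusion_frequency(ev, total_time_s = 300)
  expect_equal(unname(fr["overall"]), 5 / 300)
  expect_equal(unname(fr["overall"]), 1 / 60)
  expect_equal(unname(fr["transient"]), 1 / 300)
  expect_equal(unname(fr["stable"]), 4 / 300)   # long-life counts as stable
  expect_equal(unname(fr["long_life"]), 1 / 300)
})

test_that("protrusion NMII levels and localization lifetimes follow the rules", {
  trace <- data.frame(frame = 1:8, center = 10L, rate = 1)
  I <- matrix(1.5, 8, 100); N <- matrix(1, 8, 100)
  out <- protrusion_nmii(trace, 8L, I, N, frame_interval = 6, thresholds = 1.1)
  expect_equal(out$mean_level, 1.5)
  # constant level above threshold -> localization = full lifetime
  expect_equal(unname(out$localization_lifetime_s), 8 * 6)
  # runs of 2 and 4 frames above threshold -> longest run wins
  lvl <- c(2, 2, 0.5, 2, 2, 2, 2, 0.5)
  I2 <- matrix(rep(lvl, 100), 8, 100)
  out2 <- protrusion_nmii(trace, 8L, I2, N, 6, thresholds = 1.1)
  expect_equal(unname(out2$localization_lifetime_s), 4 * 6)
  # censored events are excluded
  out3 <- protrusion_nmii(trace, NA_integer_, I, N, 6)
  expect_true(out3$excluded)
})

test_that("front-pool protrusions carry more NMII than the sides", {
  sch <- data.frame(birth_frame = 3, angle = 0, amplitude = 2,
                    e_duration = 12, s_duration = 24, r_duration = 12)
  p <- simulation_params(n_frames = 13, centroid_speed = 0, seed = 15,
                         protrusion_schedule = sch,
                         rear_pool_level = 0.3, front_pool_level = 2,
                         front_pool_fluctuation = 0)
  walk <- centroid_walk(p)
  p$protrusion_schedule$angle <- walk$headings[3] %% (2 * pi)
  cell <- simulate_cell(p)
  dyn <- dyn_of(cell, p)
  ps <- detect_protrusions(dyn$kappa, dyn$trackings, dyn$area, p$frame_interval)
  expect_gte(nrow(ps$events), 1L)
  ev <- ps$events[1, ]
  nm <- protrusion_nmii(ps$traces[[1]], ev$lifetime_frames,
                        dyn$norm$I, cell$section_voxels, p$frame_interval)
  side_levels <- unlist(lapply(ev$Frame:(ev$Frame + ev$lifetime_frames - 1L),
                               function(t) {
    rg <- dyn$regions[[t]]
    if (!rg$defined) return(NULL)
    region_level(dyn$norm$I[t, ], cell$section_voxels[t, ],
                 c(rg$side_left, rg$side_right))
  }))
  expect_gt(nm$mean_level, mean(side_levels))
})
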