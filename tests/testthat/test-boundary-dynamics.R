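test_that("uniform dilation gives uniform positive motion and the annulus area", {
  r <- 6; delta <- 0.5
  a <- make_circle(r = r); b <- make_circle(r = r + delta)
  tr <- track_boundary_points(a, b)
  expect_equal(tr$shift, 0L)
  expect_equal(tr$motion, rep(delta, 100), tolerance = 1e-6)
  ac <- local_area_change(a, b, tr)
  expect_equal(sum(ac$area), pi * ((r + delta)^2 - r^2), tolerance = 0.005)
  expect_false(any(ac$self_intersecting))
})

test_that("pure translation yields signed motions that cancel", {
  a <- make_smooth_shape(seed = 7)
  b <- sweep(a, 2, c(0.4, -0.2), `+`)
  tr <- track_boundary_points(a, b)
  # oracle: exact point-in-polygon decides every sign
  inside <- protrudyn:::points_in_polygon(a, b[tr$correspondence, ])
  expect_equal(tr$motion < 0, inside)
  expect_lt(abs(sum(tr$motion)) / sum(abs(tr$motion)), 0.05)
  ac <- local_area_change(a, b, tr)
  expect_lt(abs(sum(ac$area)) / sum(abs(ac$area)), 0.05)
})

test_that("a growing bump localizes positive motion at the bump", {
  sch <- data.frame(birth_frame = 2, angle = 0, amplitude = 2,
                    e_duration = 6, s_duration = 12, r_duration = 12)
  p <- simulation_params(n_frames = 5, centroid_speed = 0,
                         protrusion_schedule = sch, seed = 3)
  cell <- simulate_cell(p)
  tr <- track_boundary_points(cell$boundaries[1, , ], cell$boundaries[2, , ])
  at_bump <- abs(atan2(sin(2 * pi * (0:99) / 100), cos(2 * pi * (0:99) / 100))) <
    p$bump_width
  expect_gt(min(tr$motion[at_bump & abs(2 * pi * (0:99) / 100) < 0.2]), 0.5)
  expect_lt(max(abs(tr$motion[!at_bump])), 1e-6)
})

test_that("static boundaries give zero area change", {
  a <- make_smooth_shape(seed = 2)
  ac <- local_area_change(a, a)
  expect_equal(ac$area, rep(0, 100))
})

test_that("summed local area changes track the total polygon area change", {
  worst <- 0
  th <- 2 * pi * (0:99) / 100
  for (s in 1:50) {
    set.seed(s)
    r <- rep(6, 100)
    for (m in 1:4) r <- r + runif(1, 0, 0.4) * cos(m * th + runif(1, 0, 2 * pi))
    a <- cbind(r * cos(th), r * sin(th))
    set.seed(s + 1000)
    # smooth deformation in the shape's own radial parametrization, with a
    # net dilation so the denominator is well away from zero
    d <- 0.3 + 0.15 * cos(th + runif(1, 0, 2 * pi)) +
      0.1 * cos(2 * th + runif(1, 0, 2 * pi)) +
      0.05 * cos(3 * th + runif(1, 0, 2 * pi))
    b <- cbind((r + d) * cos(th), (r + d) * sin(th))
    dA <- protrudyn:::polygon_area(b) - protrudyn:::polygon_area(a)
    ac <- local_area_change(a, b)
    rel <- abs(sum(ac$area) - dA) / abs(dA)
    worst <- max(worst, rel)
  }
  expect_lt(worst, 0.05)
})

test_that("curvature of circles and lines matches closed forms", {
  expect_equal(local_curvature(make_circle(r = 2)), rep(0.5, 100),
               tolerance = 1e-3)
  expect_equal(local_curvature(make_circle(r = 6)), rep(1 / 6, 100),
               tolerance = 1e-3)
  # straight segment: collinear Pratt window -> zero curvature
  seg <- cbind(seq(0, 10, length.out = 11), 0)
  fit <- pratt_circle_fit(seg)
  expect_false(is.finite(fit$radius) && fit$radius < 1e6)
})

test_that("Pratt fit matches the geometric least-squares oracle on arcs", {
  worst <- 0
  set.seed(99)
  for (i in 1:100) {
    r <- runif(1, 1, 10)
    ctr <- runif(2, -5, 5)
    th0 <- runif(1, 0, 2 * pi)
    th <- th0 + seq(0, runif(1, 0.5, 2.5), length.out = 11)
    pts <- cbind(ctr[1] + r * cos(th), ctr[2] + r * sin(th))
    pr <- pratt_circle_fit(pts)
    ge <- geometric_circle_fit(pts)
    worst <- max(worst, abs(pr$radius - ge$radius) / ge$radius)
  }
  expect_lt(worst, 1e-6)
})

test_that("curvature is positive on bumps and negative in concavities", {
  sch <- data.frame(birth_frame = 1, angle = 0, amplitude = 2,
                    e_duration = 6, s_duration = 30, r_duration = 12)
  p <- simulation_params(n_frames = 3, centroid_speed = 0,
                         protrusion_schedule = sch, seed = 3)
  cell <- simulate_cell(p)
  k <- local_curvature(cell$boundaries[2, , ])
  expect_gt(k[1], 0.3)              # bump apex (point 1 is at angle 0)
  # shoulders of a raised-cosine bump on a circle are concave
  expect_lt(min(k), 0)
})

test_that("cortical sections conserve voxels and find the rear pool", {
  p <- simulation_params(n_frames = 4, centroid_speed = 0.15,
                         direction_persistence = 1, seed = 17,
                         noise_gaussian_sd = 0, noise_poisson_gain = 0)
  cell <- simulate_cell(p)
  tl <- render_movie(cell)
  d <- dim(tl$data)
  t <- 1L
  vol <- array(tl$data[t, 1, , , , drop = TRUE], c(1, d[4], d[5]))
  lab <- segment_frame(tl$data[t, 1, , , , drop = TRUE])
  bd <- extract_boundary(vol, lab, voxel_size = tl$voxel_size)
  mask <- array(lab == 1L, c(1, d[4], d[5]))
  cs <- build_cortical_sections(bd$points, vol, mask, tl$voxel_size)
  expect_length(cs$I_raw, 100L)
  expect_equal(sum(cs$N) + cs$N_unassigned, sum(mask))
  expect_true(all(cs$I_raw >= min(cs$I_raw, na.rm = TRUE), na.rm = TRUE))
  # the brightest section sits in the ground-truth rear arc
  ctr <- protrudyn:::polygon_centroid(bd$points)
  ang <- atan2(bd$points[, 2] - ctr[2], bd$points[, 1] - ctr[1])
  rear_dir <- cell$headings[t] + pi
  dang <- atan2(sin(ang - rear_dir), cos(ang - rear_dir))
  expect_lt(abs(dang[which.max(cs$I_raw)]), 0.3 * pi)
})

test_that("uniform-intensity cells give uniform section intensities", {
  p <- simulation_params(n_frames = 2, centroid_speed = 0, seed = 5,
                         rear_pool_level = 0, front_pool_level = 0,
                         front_pool_fluctuation = 0, psf_sigma = 0,
                         noise_gaussian_sd = 0, noise_poisson_gain = 0)
  cell <- simulate_cell(p)
  tl <- render_movie(cell)
  d <- dim(tl$data)
  vol <- array(tl$data[1, 1, , , , drop = TRUE], c(1, d[4], d[5]))
  lab <- segment_frame(tl$data[1, 1, , , , drop = TRUE])
  bd <- extract_boundary(vol, lab, voxel_size = tl$voxel_size)
  mask <- array(lab == 1L, c(1, d[4], d[5]))
  cs <- build_cortical_sections(bd$points, vol, mask, tl$voxel_size)
  expect_lt(stats::sd(cs$I_raw) / mean(cs$I_raw), 0.05)
})

test_that("normalization pins the global minimum to 0 and the mean to 1", {
  set.seed(8)
  I_raw <- matrix(runif(10 * 100, 1, 3), 10, 100)
  N <- matrix(sample(5:20, 1000, replace = TRUE), 10, 100)
  I_mean <- rowMeans(I_raw) * 0.9
  out <- normalize_nmii(I_raw, N, I_mean)
  expect_identical(min(out$I), 0)
  # a section exactly at the cell mean maps to 1
  I_raw2 <- I_raw; I_raw2[3, 7] <- I_mean[3]
  out2 <- normalize_nmii(I_raw2, N, I_mean)
  expect_equal(out2$I[3, 7], 1)
  # affine intensity rescaling leaves I unchanged
  out3 <- normalize_nmii(3.7 * I_raw + 11, N, 3.7 * I_mean + 11)
  expect_equal(out3$I, out$I, tolerance = 1e-10)
  # flat cell is flagged
  flat <- normalize_nmii(matrix(2, 3, 100), matrix(1, 3, 100), rep(2, 3))
  expect_equal(flat$flagged_frames, 1:3)
})

test_that("smoothing uses the k-2..k+1 window, voxel-weighted", {
  I_raw <- matrix(rep(1:100, 2), 2, 100, byrow = TRUE)
  N <- matrix(1, 2, 100)
  out <- normalize_nmii(I_raw, N, rowMeans(I_raw))
  # equal weights degrade to the arithmetic mean over k-2..k+1
  k <- 50
  expect_equal(out$I_smooth[1, k], mean(out$I[1, 48:51]))
  # symmetric variant averages k-2..k+2
  outs <- normalize_nmii(I_raw, N, rowMeans(I_raw), window = "symmetric")
  expect_equal(outs$I_smooth[1, k], mean(out$I[1, 48:52]))
  # voxel weighting: doubling one neighbour's N pulls the average toward it
  N2 <- N; N2[, 48] <- 10
  outw <- normalize_nmii(I_raw, N2, rowMeans(I_raw))
  expect_lt(outw$I_smooth[1, k], out$I_smooth[1, k])
})

test_that("region partition is 30/30/20/20 with the rear opposing motion", {
  pts <- make_circle(r = 6)
  rg <- assign_regions(pts, c(1, 0))          # moving along +x
  expect_length(rg$front, 30L)
  expect_length(rg$rear, 30L)
  expect_length(rg$side_left, 20L)
  expect_length(rg$side_right, 20L)
  all_idx <- c(rg$front, rg$rear, rg$side_left, rg$side_right)
  expect_setequal(all_idx, 1:100)
  expect_equal(anyDuplicated(all_idx), 0L)
  # rear arc centred at angle 180 deg, front at 0
  ang <- atan2(pts[, 2], pts[, 1])
  expect_true(all(abs(abs(ang[rg$rear]) - pi) < 0.31 * pi))
  expect_true(all(abs(ang[rg$front]) < 0.31 * pi))
  # widths: span perpendicular to +x of a 30-point arc of a 6 um circle
  expect_equal(rg$rear_width, diff(range(pts[rg$rear, 2])))
  # undefined direction flags the frame
  und <- assign_regions(pts, c(NA, NA))
  expect_false(und$defined)
  expect_true(all(und$region == "undefined"))
})

test_that("rear-enriched synthetic pools appear in the region levels", {
  fx <- make_protrusive_cell(seed = 23, n_frames = 12)
  cell <- fx$cell
  dyn <- analyze_boundary_series(cell$boundaries, fx$params$frame_interval,
                                 I_raw = cell$section_intensity,
                                 N = cell$section_voxels,
                                 I_raw_mean = cell$cell_mean_intensity)
  ft <- dyn$frame_table
  ok <- !is.na(ft$I_front)
  expect_true(all(ft$I_rear[ok] > ft$I_front[ok]))
  expect_true(all(ft$I_front[ok] > ft$I_side[ok]))
  # region sizes constant across frames
  for (rg in dyn$regions) if (rg$defined) {
    expect_length(rg$front, 30L); expect_length(rg$rear, 30L)
  }
})
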