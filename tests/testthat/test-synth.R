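test_that("degenerate phantom volume renders the background level exactly", {
  spec <- quiet_spec(oscillation_amplitude = 0, n_frames = 3,
                     shell_radius = 40, shell_thickness = 12,
                     cylinder_height = 20, voxel_spacing = 4)
  ph <- generate_phantom_volume(spec)
  for (f in ph$volume$frames) {
    shell <- f > 0
    expect_gt(sum(shell), 100)
    expect_true(all(f[shell] == spec$background_level))
    expect_true(all(f[!shell] == 0))
    expect_true(all(f <= 65535))
  }
})

test_that("phantom generators are bit-identical for identical specs", {
  spec <- phantom_spec(n_frames = 4, shell_radius = 40, shell_thickness = 12,
                       cylinder_height = 20, voxel_spacing = 4, noise_sd = 30,
                       rng_seed = 99L)
  v1 <- generate_phantom_volume(spec)
  v2 <- generate_phantom_volume(spec)
  expect_identical(v1$volume$frames, v2$volume$frames)
  k1 <- generate_phantom_kymograph(spec)
  k2 <- generate_phantom_kymograph(spec)
  expect_identical(k1$kymo$mat, k2$kymo$mat)
  t1 <- generate_phantom_tracks(spec, n_tracks = 7)
  t2 <- generate_phantom_tracks(spec, n_tracks = 7)
  expect_identical(t1$tracks, t2$tracks)
})

test_that("uniform-period shell follows the closed-form intensity model", {
  spec <- quiet_spec(proximal_period = 150, distal_period = 150,
                     n_frames = 5, shell_radius = 40, shell_thickness = 12,
                     cylinder_height = 20, voxel_spacing = 4)
  ph <- generate_phantom_volume(spec)
  a <- spec$oscillation_amplitude
  for (j in seq_along(ph$volume$frames)) {
    t <- (j - 1) * spec$frame_interval_dt
    f <- ph$volume$frames[[j]]
    shell <- f > 0
    expected <- spec$background_level + a * (1 + cos(2 * pi * t / 150)) / 2
    expect_equal(unique(round(f[shell], 9)), round(expected, 9))
  }
})

test_that("oversized shells are rejected with a sizing message", {
  spec <- quiet_spec(n_frames = 3, shell_radius = 90, voxel_spacing = 2.088)
  expect_error(generate_phantom_volume(spec, vol_dim = c(30, 30, 30)),
               "cannot contain the shell")
})

test_that("kymograph phantom reproduces the analytic phase gradient", {
  spec <- quiet_spec(proximal_period = 130, distal_period = 150,
                     n_frames = 60)
  g <- generate_phantom_kymograph(spec)
  # analytic phase difference between arc ends at t = 390 min
  t <- 390
  l <- g$truth$arc_length(t)
  dphi <- g$truth$phase(0, t) - g$truth$phase(l, t)
  expect_equal(dphi, 2 * pi * t * (1 / 130 - 1 / 150), tolerance = 1e-12)
  # numeric phase integration as an independent oracle
  ts <- seq(0, t, by = 0.01)
  int_prox <- sum(2 * pi / g$truth$period(0, ts)) * 0.01
  int_dist <- sum(2 * pi / g$truth$period(l, ts)) * 0.01
  expect_equal(dphi, int_prox - int_dist, tolerance = 1e-3)
  # rendered rows match the model: row at distance s carries cos(phi(s, t))
  j <- 40; tj <- (j - 1) * 10
  r <- g$kymo$midline_row - 50  # 50 px into the left side
  s <- 50 * g$kymo$spatial_pixel
  expect_equal(g$kymo$mat[r, j],
               spec$background_level + spec$oscillation_amplitude *
                 (1 + cos(g$truth$phase(s, tj))) / 2,
               tolerance = 1e-9)
})

test_that("uniform static kymograph rows are identical sinusoids", {
  spec <- quiet_spec(proximal_period = 150, distal_period = 150,
                     n_frames = 30)
  g <- generate_phantom_kymograph(spec)
  valid_rows <- which(g$kymo$valid[, 1])
  ref <- g$kymo$mat[valid_rows[1], ]
  for (r in valid_rows) expect_equal(g$kymo$mat[r, ], ref)
})

test_that("out-of-domain kymograph cells carry the fill value, growth is bounded", {
  spec <- phantom_spec(noise_sd = 0, pulse_amplitude = 0, growth_rate = 0.2,
                       n_frames = 50, rng_seed = 5L)
  g <- generate_phantom_kymograph(spec)
  expect_true(all(g$kymo$mat[!g$kymo$valid] == 1067))
  # arc grows: more valid rows at the end than at the start
  expect_gt(sum(g$kymo$valid[, 50]), sum(g$kymo$valid[, 1]))
  # matrix too small for the final arc is rejected
  expect_error(generate_phantom_kymograph(spec, n_side_rows = 100L),
               "rows")
})

test_that("jitter-free tracks advect at exactly the configured speed", {
  spec <- phantom_spec(advection_speed = 0.2, rng_seed = 3L, n_frames = 40)
  tk <- generate_phantom_tracks(spec, n_tracks = 4, jitter_sd = 0)
  rm <- spec$shell_radius - spec$shell_thickness / 2
  for (id in 1:4) {
    tr <- tk$tracks[tk$tracks$track_id == id, ]
    s <- wavekymo:::shell_arc_coord(cbind(tr$z_um, tr$y_um, tr$x_um),
                                    tk$truth$center, rm)
    expect_lt(max(abs(diff(s) / spec$frame_interval_dt - 0.2)), 1e-9)
  }
  # zero speed, zero jitter: stationary
  tk0 <- generate_phantom_tracks(phantom_spec(advection_speed = 0,
                                              rng_seed = 3L, n_frames = 10),
                                 n_tracks = 3, jitter_sd = 0)
  for (id in 1:3) {
    tr <- tk0$tracks[tk0$tracks$track_id == id, ]
    expect_equal(diff(tr$x_um), rep(0, nrow(tr) - 1))
    expect_equal(diff(tr$y_um), rep(0, nrow(tr) - 1))
    expect_equal(diff(tr$z_um), rep(0, nrow(tr) - 1))
  }
  # default speeds drawn from the reported motility range
  tkd <- generate_phantom_tracks(phantom_spec(rng_seed = 8L), n_tracks = 20)
  expect_true(all(tkd$truth$track_velocities >= 0.1 &
                    tkd$truth$track_velocities <= 0.3))
})

test_that("analytic q(t) matches numeric integration of instantaneous frequency", {
  spec <- quiet_spec(proximal_period = 133, distal_period = 153, n_frames = 10)
  g <- generate_phantom_kymograph(spec)
  tt <- seq(0, 900, by = 100)
  q_analytic <- g$truth$q(tt)
  expect_true(all(diff(q_analytic) >= 0))  # nondecreasing for P_prox <= P_dist
  expect_equal(g$truth$q(0), 0)
  expect_equal(g$truth$phase(0, 0), 0)
  l <- g$truth$arc_length(0)
  expect_equal(g$truth$phase(l / 3, 0), 0)
  for (t in tt) {
    ts <- seq(0, t, length.out = 2001)
    h <- if (t > 0) ts[2] - ts[1] else 0
    dq <- (1 / g$truth$period(0, ts) - 1 / g$truth$period(g$truth$arc_length(ts), ts))
    q_num <- if (t > 0) (sum(dq) - (dq[1] + dq[2001]) / 2) * h else 0
    expect_equal(g$truth$q(t), q_num, tolerance = 1e-6)
  }
})
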