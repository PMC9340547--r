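test_that("landmark interpolation is linear with clamped extrapolation", {
  lm <- landmark_set(
    times = c(0, 10, 30),
    origin = rbind(c(0, 0, 0), c(10, 0, 0), c(30, 20, 0)),
    left_distal = rbind(c(0, 5, 0), c(10, 5, 0), c(30, 5, 0)),
    right_distal = rbind(c(0, -5, 0), c(10, -5, 0), c(30, -5, 0)))
  out <- interpolate_landmarks(lm, c(-5, 0, 5, 10, 20, 30, 99))
  expect_equal(out$origin[3, ], c(5, 0, 0))          # midpoint of keyframes
  expect_equal(out$origin[5, ], c(20, 10, 0))        # linear between 10 and 30
  expect_equal(out$origin[2, ], c(0, 0, 0))          # exact at a keyframe
  expect_equal(out$origin[1, ], c(0, 0, 0))          # clamped before the span
  expect_equal(out$origin[7, ], c(30, 20, 0))        # clamped after the span
  expect_error(landmark_set(c(10, 10), rbind(c(0, 0, 0), c(0, 0, 0)),
                            rbind(c(0, 1, 0), c(0, 1, 0)),
                            rbind(c(0, -1, 0), c(0, -1, 0))),
               "strictly increasing")
})

test_that("ray casting finds the shell radius and smooths linear motion", {
  vol <- shell_volume(r_peak = 32)
  com <- (dim(vol$frames[[1]]) - 1) / 2 * vol$spacing
  n_t <- length(vol$frames)
  org <- matrix(rep(com + c(-32, 0, 0), n_t), ncol = 3, byrow = TRUE)
  dis <- matrix(rep(com + c(0, 32, 0), n_t), ncol = 3, byrow = TRUE)
  ip <- locate_intermediate_point(vol, com, org, dis)
  r_found <- sqrt(sum((ip$points[1, ] - com)^2))
  expect_lt(abs(r_found - 32), vol$spacing[1])  # at the peak within one voxel
  # constant intensity along the ray: the sample closest to the COM wins
  flat <- volume_series(list(array(100, c(11, 11, 11))), spacing = 1, dt = 1)
  ipf <- locate_intermediate_point(flat, c(5, 5, 5),
                                   matrix(c(5, 9, 5), 1), matrix(c(9, 5, 5), 1))
  expect_equal(ipf$raw[1, ], c(5, 5, 5))
  # degenerate ray (COM at the midpoint) errors
  expect_error(locate_intermediate_point(flat, c(5, 5, 5),
                                         matrix(c(4, 5, 5), 1),
                                         matrix(c(6, 5, 5), 1)),
               "degenerate")
  # argmax positions on a line over time are reproduced by the spline
  expect_equal(dim(ip$points), dim(ip$raw))
  expect_lt(max(abs(ip$points - ip$raw)), vol$spacing[1])
})

test_that("surface paths: straight segments and circular arcs are exact", {
  # collinear anchors 50 um apart: straight segment of length 100, exactly
  p <- build_surface_path(c(0, 0, 0), c(0, 0, 50), c(0, 0, 100))
  expect_equal(p$total_length, 100, tolerance = 1e-12)
  expect_equal(p$point_at(0.25)[1, ], c(0, 0, 25), tolerance = 1e-9)
  # quarter-circle anchors at 0, 45, 90 degrees, r = 100
  r <- 100
  q <- build_surface_path(c(0, 0, r), c(0, r / sqrt(2), r / sqrt(2)),
                          c(0, r, 0), n_segments = 100000L)
  expect_lt(abs(q$total_length - pi * r / 2) / (pi * r / 2), 0.005)
  # anchors are interpolated exactly
  expect_equal(q$point_at(0)[1, ], c(0, 0, r), tolerance = 1e-9)
  expect_equal(q$point_at(1)[1, ], c(0, r, 0), tolerance = 1e-9)
  expect_lt(min(sqrt(rowSums(sweep(q$point_at(seq(0, 1, 1e-3)), 2,
                                   c(0, r / sqrt(2), r / sqrt(2)))^2))), 1e-6)
  # chord table: nondecreasing, total equals the last entry
  expect_true(all(diff(q$cum) >= 0))
  expect_equal(q$total_length, q$cum[length(q$cum)])
  expect_error(build_surface_path(c(0, 0, 0), c(0, 0, 0), c(0, 0, 1)),
               "distinct")
})

test_that("chord table converges to fine quadrature and supports lookups", {
  # parabola-like anchor triple; fine quadrature of the same curve as oracle
  p <- build_surface_path(c(0, 0, 0), c(0, 25, 50), c(0, 100, 100),
                          n_segments = 100000L)
  u <- seq(0, 1, length.out = 400001)
  pts <- p$point_at(u)
  quad <- sum(sqrt(rowSums((pts[-1, ] - pts[-nrow(pts), ])^2)))
  expect_lt(abs(p$total_length - quad) / quad, 1e-3)
  # integer-distance lookup lands within one segment length of the target
  d <- 0:floor(p$total_length)
  lk <- arc_lookup(p, d)
  seg_len <- p$total_length / p$n_segments
  expect_lt(max(abs(lk$cum_length - d)), seg_len)
  expect_true(all(lk$u >= 0 & lk$u <= 1))
  expect_true(is.na(arc_lookup(p, p$total_length + 5)$u))
})

test_that("surface kymograph reproduces arc-distance intensity profiles", {
  # axisymmetric phantom: intensity is a known linear function of arc
  spec <- quiet_spec(n_frames = 2, shell_radius = 50, shell_thickness = 16,
                     cylinder_height = 30, voxel_spacing = 2,
                     oscillation_amplitude = 0)
  ph <- generate_phantom_volume(spec)
  vol <- ph$volume
  # overwrite intensity: background + arc distance (via the truth geometry)
  rm <- spec$shell_radius - spec$shell_thickness / 2
  cen <- ph$truth$center
  d <- dim(vol$frames[[1]])
  g <- expand.grid(z = (1:d[1] - 1) * 2, y = (1:d[2] - 1) * 2,
                   x = (1:d[3] - 1) * 2)
  s <- wavekymo:::shell_arc_coord(as.matrix(g), cen, rm)
  for (j in 1:2) {
    f <- vol$frames[[j]]
    f[f > 0] <- 1000 + array(s, d)[f > 0]
    vol$frames[[j]] <- f
  }
  paths <- phantom_paths(ph$truth, frame_times(vol), n_segments = 20000L)
  km <- sample_surface_kymograph(vol, paths$left, paths$right,
                                 smoothing_sigma_px = 0,
                                 sphere_diameter_px = 6)
  rows <- which(km$valid[, 1])
  dist_px <- abs(rows - km$midline_row) * km$spatial_pixel
  vals <- km$mat[rows, 1]
  # row r tracks 1000 + arc distance, within the sphere-averaging blur
  err <- abs(vals - (1000 + dist_px))
  expect_lt(stats::median(err), 2)
  # the sphere mean blurs across the shell near the cap-cylinder junction,
  # where the fitted arc deviates most from the meridian
  expect_lt(max(err[dist_px > 10 & dist_px < max(dist_px) - 10]), 10)
  # symmetry about the midline for this symmetric phantom
  up <- km$mat[km$midline_row - 1:30, 1]
  down <- km$mat[km$midline_row + 1:30, 1]
  expect_equal(up, down, tolerance = 1e-9)
})

test_that("sphere mean of a constant field is exactly the constant", {
  a <- array(123.5, c(30, 30, 30))
  vol <- volume_series(list(a), spacing = 1, dt = 1)
  path <- build_surface_path(c(15, 15, 5), c(15, 18, 15), c(15, 15, 25),
                             n_segments = 1000L)
  km <- sample_surface_kymograph(vol, list(path), list(path),
                                 smoothing_sigma_px = 0)
  expect_true(all(km$mat[km$valid] == 123.5))
})

test_that("MIP kymograph handles constants and rejects wide corridors", {
  a <- array(42, c(20, 20, 20))
  vol <- volume_series(list(a), spacing = 2, dt = 1)
  path <- build_surface_path(c(2, 10, 2), c(20, 12, 20), c(36, 10, 36),
                             n_segments = 1000L)
  km <- mip_kymograph(vol, list(path), axis = "y", corridor_um = 10,
                      gaussian_sigma_um = 4)
  expect_true(all(abs(km$mat[km$valid] - 42) < 1e-9))
  expect_error(mip_kymograph(vol, list(path), axis = "y", corridor_um = 500),
               "corridor")
})

test_that("transverse sections project the requested slab", {
  a <- array(0, c(30, 12, 12))
  a[15, 4, 7] <- 900  # bright voxel at z slab center
  vol <- volume_series(list(a), spacing = c(2, 1, 1), dt = 1)
  # domain spans z 0..56 um; fraction 0.5 -> 28 um -> voxel z = 15
  sec <- transverse_section(vol, 1, domain_z_range = c(0, 56),
                            proximodistal_fraction = 0.5, slab_um = 12)
  expect_equal(dim(sec), c(12, 12))
  expect_equal(sec[4, 7], 900)
  expect_equal(sum(sec > 0), 1)
  # a slab of one voxel plane is a plain slice
  one <- transverse_section(vol, 1, domain_z_range = c(0, 56),
                            proximodistal_fraction = 0.5, slab_um = 2)
  expect_equal(one, a[15, , ])
  expect_error(transverse_section(vol, 1, domain_z_range = NULL),
               "domain")
  expect_error(transverse_section(vol, 1, c(0, 56), proximodistal_fraction = 2),
               "fraction")
})

test_that("kymograph line profiles average the configured stripe", {
  g <- generate_phantom_kymograph(quiet_spec(n_frames = 20))
  km <- g$kymo
  pr <- kymo_profile(km, "time", km$midline_row, stripe_px = 10L)
  # midline stripe of a valid region equals the plain row mean
  expect_equal(pr, colMeans(km$mat[km$midline_row + (-4:5), ]))
  sp <- kymo_profile(km, "space", 3L, stripe_px = 4L)
  expect_length(sp, nrow(km$mat))
  # static phantom: finite exactly on the valid rows, NA outside the domain
  expect_identical(is.finite(sp), km$valid[, 3])
})

test_that("profile normalization forces [0, 1] and passes smooth data through", {
  x <- seq_len(200)
  prof <- 500 + 100 * sin(x / 15)
  out <- normalize_profile(prof)
  expect_equal(min(out), 0)
  expect_equal(max(out), 1)
  # an already-smooth linear profile is reproduced by LOWESS
  lin <- 3 + 0.5 * x
  sm <- normalize_profile(lin, subtract_background = FALSE,
                          normalize_max = FALSE)
  expect_equal(sm, as.numeric(lin), tolerance = 1e-8)
  # raw pass-through mode
  raw <- normalize_profile(prof, lowess_bandwidth = NA,
                           subtract_background = FALSE, normalize_max = FALSE)
  expect_identical(raw, as.numeric(prof))
  expect_warning(z <- normalize_profile(rep(5, 10)), "constant")
  expect_equal(z, rep(0, 10))
  expect_error(normalize_profile(c(1, 2)), "length")
})
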