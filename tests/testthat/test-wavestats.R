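test_that("wave number: definition, gauge invariance, degenerate columns", {
  px <- 2.088
  # spatially uniform phase -> q = 0
  pk0 <- toy_phase_kymograph(phi_fun = function(d, j) 0.7)
  expect_equal(compute_wave_number(pk0, distal_crop_px = 0L)$q, rep(0, 4))
  # phase rising linearly from 0 at the midline to 2*pi at the distal end
  n_side <- 30
  pk1 <- toy_phase_kymograph(n_side = n_side, phi_fun = function(d, j) {
    wavekymo:::wrap_phase(2 * pi * d / n_side)
  })
  expect_equal(compute_wave_number(pk1, distal_crop_px = 0L)$q, rep(1, 4),
               tolerance = 1e-9)
  # gauge invariance: adding a constant phase to every cell leaves q alone
  pk2 <- toy_phase_kymograph(n_side = n_side, phi_fun = function(d, j) {
    wavekymo:::wrap_phase(2 * pi * d / n_side + 1.234)
  })
  expect_equal(compute_wave_number(pk2, distal_crop_px = 0L)$q,
               compute_wave_number(pk1, distal_crop_px = 0L)$q,
               tolerance = 1e-9)
  # cropping shortens the measured span accordingly
  q_crop <- compute_wave_number(pk1, distal_crop_px = 10L)
  expect_equal(q_crop$q, rep((n_side - 10) / n_side, 4), tolerance = 1e-9)
  # fewer than 2 valid cells after cropping -> flagged NA
  pk3 <- toy_phase_kymograph(n_side = 5)
  pk3$valid[, 2] <- FALSE
  q3 <- compute_wave_number(pk3, distal_crop_px = 0L,
                            side = "left")
  expect_true(is.na(compute_wave_number(pk3, distal_crop_px = 5L)$q[1]))
  expect_true(is.na(q3$q[2]))
})

test_that("measured q(t) follows the analytic wave-number growth", {
  spec <- quiet_spec(proximal_period = 130, distal_period = 150,
                     n_frames = 120)
  g <- generate_phantom_kymograph(spec)
  pk <- make_phase_kymograph(g$kymo, onset_frame = 1)
  # full-domain measurement against the analytic q(t)
  q <- compute_wave_number(pk, distal_crop_px = 0L)
  sel <- q$time <= 800
  expect_lt(max(abs(q$q - g$truth$q(q$time))[sel], na.rm = TRUE), 0.05)
  # with the default 20 px distal crop the measured span ends short of the
  # distal anchor; compare against the analytic q over the measured span
  q20 <- compute_wave_number(pk, distal_crop_px = 20L)
  s_end <- (q20$n_rows - 1) * pk$spatial_pixel
  p_end <- g$truth$period(s_end, q20$time)
  qa <- q20$time * (1 / 130 - 1 / p_end)
  expect_lt(max(abs(q20$q - qa)[sel], na.rm = TRUE), 0.05)
  # slope = q / L is strictly increasing on the static domain
  ws <- wave_stats(pk)
  s2 <- ws$time > 0 & ws$time <= 800
  expect_true(all(diff(ws$slope[s2]) > 0))
  # slope * L reconstructs q exactly at every timepoint
  expect_equal(ws$slope * ws$L_um, ws$q, tolerance = 1e-12)
})

test_that("mesoderm length: arithmetic, growth recovery, path variant", {
  # 250 valid rows after crop at 2.088 um/px -> 522 um
  pk <- toy_phase_kymograph(n_side = 270, phi_fun = function(d, j) 0)
  l <- mesoderm_length(pk, distal_crop_px = 21L)
  expect_equal(l$L_um, rep(250 * 2.088, 4))
  # static phantom: L constant; growing phantom: dL/dt ~ growth rate
  spec <- phantom_spec(noise_sd = 0, pulse_amplitude = 0, growth_rate = 0.2,
                       n_frames = 60, rng_seed = 2L)
  g <- generate_phantom_kymograph(spec)
  lk <- mesoderm_length(g$kymo, distal_crop_px = 0L)
  fit <- stats::coef(stats::lm(lk$L_um ~ lk$time))[[2]]
  expect_lt(abs(fit - 0.2), g$kymo$spatial_pixel / spec$frame_interval_dt)
  spec0 <- quiet_spec(n_frames = 20)
  g0 <- generate_phantom_kymograph(spec0)
  expect_equal(length(unique(mesoderm_length(g0$kymo)$L_um)), 1L)
  # path-based variant
  paths <- list(line_path(), line_path())
  lp <- mesoderm_length(paths, distal_crop_px = 0L, spatial_pixel = 2)
  expect_equal(lp$L_um, rep((floor(600 / 2) + 1) * 2, 2))
  expect_error(mesoderm_length(list(1, 2)), "path")
})

test_that("phase-gradient slope is q over L with safe degenerate handling", {
  expect_equal(compute_phase_gradient_slope(1, 500), 0.002)
  expect_equal(compute_phase_gradient_slope(c(0, 0.5), c(100, 250)),
               c(0, 0.002))
  expect_true(is.na(compute_phase_gradient_slope(1, 0)))
  expect_true(is.na(compute_phase_gradient_slope(NA, 100)))
  expect_error(compute_phase_gradient_slope(1:3, 1:2), "aligned")
})

test_that("period-gradient sampling recovers the phantom gradient", {
  # uniform phantom: proximal and distal medians agree within a minute
  spec_u <- phantom_spec(proximal_period = 140, distal_period = 140,
                         noise_sd = 10, pulse_amplitude = 0, growth_rate = 0.2,
                         rng_seed = 21L, n_frames = 100)
  gu <- generate_phantom_kymograph(spec_u)
  pgu <- sample_period_gradient(gu$kymo, onset_frame = 1)
  expect_lt(abs(diff(pgu$summary$median)), 1)
  # default study conditions: 133 vs 153 min with growth and noise
  spec <- phantom_spec(rng_seed = 11L)
  g <- generate_phantom_kymograph(spec)
  pg <- sample_period_gradient(g$kymo, onset_frame = 1)
  expect_equal(pg$summary$n, c(24L, 24L))  # 24 samples per region at dt = 10
  expect_lt(abs(pg$summary$median[1] - 133), 5)
  expect_lt(abs(pg$summary$median[2] - 153), 5)
  expect_lt(abs(diff(pg$summary$median) - 20), 5)
  # median/IQR agree with a brute-force sort-based oracle
  x <- pg$distal$period
  n <- length(x)
  srt <- sort(x)
  qt <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    srt[lo] + (h - lo) * (srt[hi] - srt[lo])
  }
  expect_equal(pg$summary$median[2], qt(0.5))
  expect_equal(pg$summary$iqr[2], qt(0.75) - qt(0.25))
  # a window longer than the recording is refused
  expect_error(sample_period_gradient(g$kymo, onset_frame = 1,
                                      window = c(120, 1e5)),
               "window")
})
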