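test_that("configuration validation enforces defaults and constraints", {
  cfg <- pipeline_config()
  expect_s3_class(cfg, "pipeline_config")
  expect_equal(cfg$mask_threshold, 1030)
  expect_equal(cfg$background_offset, 1000)
  expect_equal(cfg$n_segments, 100000L)
  expect_equal(cfg$fill_value, 1067)
  expect_equal(cfg$period_range, c(100, 220))
  expect_equal(cfg$cutoff_period, 220)
  expect_equal(cfg$distal_crop_px, 20L)
  expect_equal(cfg$corridor_px, 8L)
  expect_equal(cfg$period_window, c(120, 360))
  expect_equal(cfg$track_radius_um, 30)
  expect_equal(cfg$track_min_consecutive_min, 300)
  expect_equal(cfg$onset_offset_min, 260)
  expect_equal(cfg$spatial_pixel, 2.088)
  # unknown keys are rejected
  expect_error(pipeline_config(nonsense = 1), "unknown configuration field")
  # wavelet grid must clear the Nyquist period for the configured dt
  expect_error(pipeline_config(phantom = list(frame_interval_dt = 60)),
               "Nyquist")
  # negative frame interval is refused by the phantom validation
  expect_error(pipeline_config(phantom = list(frame_interval_dt = -1)))
  # cut-off below the top of the analysis band warns
  expect_warning(pipeline_config(cutoff_period = 150), "attenuate")
  # onset frame must index a frame in manual-onset mode
  expect_error(pipeline_config(onset_frame = 0L), "onset_frame")
  expect_error(pipeline_config(onset_frame = 1e5), "onset_frame")
})

test_that("an empty YAML config yields the full-default phantom pipeline", {
  f <- tempfile(fileext = ".yaml")
  writeLines("", f)
  cfg <- validate_config(f)
  expect_s3_class(cfg, "pipeline_config")
  expect_equal(cfg$mode, "kymograph")
  expect_equal(cfg$seed, 1L)
  # YAML overrides flow through
  writeLines(c("seed: 9", "fill_value: 1200"), f)
  cfg2 <- validate_config(f)
  expect_equal(cfg2$seed, 9)
  expect_equal(cfg2$fill_value, 1200)
})

test_that("the self-contained pipeline is deterministic to the byte", {
  d1 <- tempfile(); d2 <- tempfile()
  cfg <- list(seed = 4L, flow = TRUE, n_tracks = 12L,
              phantom = list(n_frames = 60))
  b1 <- run_pipeline(c(cfg, list(output_dir = d1)))
  b2 <- run_pipeline(c(cfg, list(output_dir = d2)))
  files <- c("kymograph.csv", "kymograph.json", "phase_kymograph.csv",
             "wave_stats.csv", "wave_stats_summary.csv",
             "period_samples.csv", "period_summary.csv", "vector_field.csv",
             "provenance.json")
  for (f in files) {
    expect_true(file.exists(file.path(d1, f)), info = f)
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7), info = f)
  }
  # the bundle carries every headline statistic with no external input
  expect_s3_class(b1$stats, "wave_stats")
  expect_true(all(c("q", "L_um", "slope") %in% names(b1$stats)))
  expect_equal(b1$period_gradient$summary$n, c(24L, 24L))
  expect_identical(b1$stats, b2$stats)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("kymograph, track, landmark and TIFF files round-trip", {
  # kymograph CSV + sidecar
  g <- generate_phantom_kymograph(quiet_spec(n_frames = 60))
  p <- file.path(tempfile(), "k")
  dir.create(dirname(p), recursive = TRUE)
  write_kymograph(g$kymo, p)
  back <- read_kymograph(p)
  expect_equal(back$mat, g$kymo$mat, tolerance = 1e-12)
  expect_equal(back$valid, g$kymo$valid)
  expect_equal(back$spatial_pixel, g$kymo$spatial_pixel)
  # phase kymograph keeps its onset and validity through the round-trip
  pk <- make_phase_kymograph(g$kymo, onset_frame = 1,
                             period_grid = default_period_grid(60))
  write_kymograph(pk, paste0(p, "_phase"))
  pb <- read_kymograph(paste0(p, "_phase"))
  expect_equal(pb$mat[pb$valid], pk$mat[pk$valid], tolerance = 1e-12)
  expect_equal(pb$onset_frame, 1L)
  # tracks
  tk <- generate_phantom_tracks(quiet_spec(n_frames = 5), n_tracks = 3)
  tf <- tempfile(fileext = ".csv")
  write_tracks(tk$tracks, tf)
  expect_equal(read_tracks(tf), tk$tracks, tolerance = 1e-12)
  # landmarks
  lm <- landmark_set(c(0, 50), rbind(c(0, 1, 2), c(3, 4, 5)),
                     rbind(c(9, 8, 7), c(6, 5, 4)),
                     rbind(c(1, 1, 1), c(2, 2, 2)),
                     rotation_angles = c(0, 10, 0))
  lp <- tempfile()
  write_landmarks(lm, lp)
  lb <- read_landmarks(lp)
  expect_equal(lb$origin, lm$origin)
  expect_equal(lb$rotation_angles, lm$rotation_angles)
  # ground truth, ridge and spectrum exports are parseable structured text
  gt <- tempfile(fileext = ".json")
  write_ground_truth(tk$truth, gt)
  gtb <- jsonlite::read_json(gt, simplifyVector = TRUE)
  expect_equal(gtb$parameters$proximal_period, 133)
  expect_equal(gtb$per_frame$q, tk$truth$q(gtb$per_frame$t_min))
  sp <- morlet_spectrum(cos(2 * pi * (0:99) / 15), dt = 10,
                        period_grid = default_period_grid(40))
  sf <- tempfile()
  write_spectrum(sp, sf)
  re <- as.matrix(utils::read.table(paste0(sf, "_re.csv"), sep = ","))
  expect_equal(unname(re), Re(sp$coef), tolerance = 1e-10)
  rf <- tempfile(fileext = ".csv")
  write_ridge(extract_ridge(sp), rf)
  expect_equal(utils::read.csv(rf)$period, extract_ridge(sp)$period)
  # 16-bit TIFF volumes (quantized to 1/65535 of the intensity range)
  ph <- generate_phantom_volume(quiet_spec(
    n_frames = 2, shell_radius = 30, shell_thickness = 10,
    cylinder_height = 15, voxel_spacing = 4))
  td <- tempfile()
  write_volume_tiff(ph$volume, td)
  vb <- read_volume_tiff(td)
  expect_equal(dim(vb), dim(ph$volume))
  expect_lt(max(abs(vb$frames[[1]] - ph$volume$frames[[1]])), 0.51)
  expect_equal(vb$spacing, ph$volume$spacing)
})

test_that("the command-line wrapper reproduces library results", {
  script <- system.file("scripts", "run-pipeline.R", package = "wavekymo")
  expect_true(nzchar(script))
  cfgf <- tempfile(fileext = ".yaml")
  writeLines(c("seed: 2", "flow: false", "phantom:", "  n_frames: 60"), cfgf)
  outdir <- tempfile()
  rscript <- file.path(R.home("bin"), "Rscript")
  res <- system2(rscript, c(script, "--config", cfgf, "--out", outdir),
                 stdout = TRUE, stderr = TRUE,
                 env = paste0("R_LIBS=", paste(.libPaths(), collapse = ":")))
  expect_true(file.exists(file.path(outdir, "wave_stats.csv")))
  lib <- run_pipeline(list(seed = 2L, flow = FALSE,
                           phantom = list(n_frames = 60L),
                           output_dir = tempfile()))
  cli_stats <- utils::read.csv(file.path(outdir, "wave_stats.csv"))
  lib_df <- as.data.frame(lib$stats)
  attr(lib_df, "summary") <- NULL
  attr(lib_df, "side") <- NULL
  class(lib_df) <- "data.frame"
  expect_equal(cli_stats, lib_df)
  unlink(outdir, recursive = TRUE)
})
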