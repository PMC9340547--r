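#' Default pipeline configuration
#'
#' Collects every tunable of the pipeline with the documented defaults: the
#' 1030-count mask threshold, 1000-count background offset, automatic
#' z-resize factor (3.59 for 7.5 um z-steps over 2.088 um pixels), 100,000
#' chord segments, 6 px volume smoothing sigma, 12 px sampling sphere,
#' 220 min sinc cut-off, 600-period wavelet grid over 100-220 min, 1067
#' fill value, 5 px spatial phase smoothing, 20 px distal crop and contour
#' shift, 8 px corridor, 2-6 h period window, 30 um / 300 min track
#' filtering, 260 min pulse-to-onset offset and 2.088 um spatial pixel.
#'
#' @param ... overrides for any configuration field (unknown names are
#'   rejected).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    mode = "kymograph",            # "kymograph" (direct render) or "volume"
    seed = 1L,
    phantom = list(),              # overrides for phantom_spec()
    vol_dim = NULL,                # volume mode: voxel dimensions (z, y, x)
    background_box = NULL,         # NULL = default corner box
    background_offset = 1000,
    reference_index = 1L,
    mask_threshold = 1030,
    rotation_angles = NULL,        # NULL = from the landmark annotation
    z_factor = "auto",
    subsample_factor = 1,
    n_segments = 100000L,
    surface_sigma_px = 6,
    sphere_diameter_px = 12,
    spatial_sigma_px = 5,
    cutoff_period = 220,
    n_periods = 600L,
    period_range = c(100, 220),
    fill_value = 1067,
    onset_frame = 1L,
    distal_crop_px = 20L,
    distal_shift_px = 20L,
    corridor_px = 8L,
    period_window = c(120, 360),
    side = "left",
    flow = TRUE,
    n_tracks = 50L,
    track_radius_um = 30,
    track_min_consecutive_min = 300,
    onset_offset_min = 260,
    spatial_pixel = 2.088,
    keep_volume = FALSE,
    output_dir = NULL
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  validate_config_impl(cfg)
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path, a plain list, or nothing (full defaults);
#' injects defaults, rejects unknown fields and enforces cross-field
#' constraints (positive physical quantities, wavelet grid above the
#' Nyquist period, detrending cut-off versus analysis band).
#'
#' @param x config YAML path, list of overrides, or `NULL` for defaults.
#' @return a validated `pipeline_config`.
#' @export
validate_config <- function(x = NULL) {
  if (inherits(x, "pipeline_config")) {
    cfg <- unclass(x)
    cfg$phantom_spec <- NULL
    return(validate_config_impl(cfg))
  }
  if (is.character(x) && length(x) == 1L) {
    raw <- yaml::read_yaml(x)
    if (is.null(raw)) raw <- list()
    return(do.call(pipeline_config, raw))
  }
  if (is.list(x)) return(do.call(pipeline_config, x))
  if (is.null(x)) return(pipeline_config())
  stop("config must be a YAML path, a list, or NULL")
}

# Core validation on a complete plain-list configuration.
validate_config_impl <- function(cfg) {
  spec <- do.call(phantom_spec, c(cfg$phantom, list(rng_seed = cfg$seed)))
  dt <- spec$frame_interval_dt
  if (dt <= 0) stop("config error: frame_interval_dt must be > 0")
  if (!cfg$mode %in% c("kymograph", "volume")) {
    stop("config error: mode must be 'kymograph' or 'volume'")
  }
  for (f in c("background_offset", "mask_threshold", "n_segments",
              "sphere_diameter_px", "cutoff_period", "n_periods",
              "fill_value", "spatial_pixel", "track_radius_um",
              "track_min_consecutive_min", "onset_offset_min")) {
    if (cfg[[f]] <= 0) stop("config error: ", f, " must be positive")
  }
  if (cfg$period_range[1] <= 2 * dt) {
    stop(sprintf(
      "config error: wavelet periods start at %g min, at or below the Nyquist period %g min",
      cfg$period_range[1], 2 * dt))
  }
  if (cfg$cutoff_period < cfg$period_range[2]) {
    warning(sprintf(
      "cut-off period %g min is below the longest wavelet period %g min; the trend filter will attenuate the upper analysis band",
      cfg$cutoff_period, cfg$period_range[2]))
  }
  if (cfg$onset_frame < 1L || cfg$onset_frame > spec$n_frames) {
    stop("config error: onset_frame must index a frame (manual-onset mode)")
  }
  if (!cfg$side %in% c("left", "right")) {
    stop("config error: side must be 'left' or 'right'")
  }
  cfg$phantom_spec <- spec
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf("<pipeline_config> mode '%s', seed %d\n", x$mode, x$seed))
  cat(sprintf("  wavelets: %d periods %g-%g min, cut-off %g min; fill %g\n",
              x$n_periods, x$period_range[1], x$period_range[2],
              x$cutoff_period, x$fill_value))
  invisible(x)
}

#' Run the phantom-to-statistics pipeline
#'
#' Executes the full quantification chain on a synthetic phantom: phantom
#' generation (direct kymograph render, or 3D volume followed by background
#' reduction, recursive registration, center-of-mass alignment, isotropic
#' resampling and surface-kymograph sampling), then phase extraction, wave
#' number / mesoderm length / phase-gradient slope, period-gradient
#' sampling, and optionally cell-track flow analysis. When `output_dir` is
#' set, every intermediate is written with a provenance sidecar echoing the
#' full configuration.
#'
#' @param config a `pipeline_config`, a list of overrides, a YAML path, or
#'   `NULL` for the defaults.
#' @return a result bundle: list with the realized `config`, the intensity
#'   `kymo`, the `phase` kymograph, `stats` ([wave_stats()]),
#'   `period_gradient`, `flow` (vector field or `NULL`), `truth` and, in
#'   volume mode, `landmarks`, per-side paths and (with
#'   `keep_volume = TRUE`) the aligned `volume`.
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- validate_config(config)
  spec <- cfg$phantom_spec
  bundle <- list(config = cfg)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  if (cfg$mode == "volume") {
    ph <- stage("synth", generate_phantom_volume(spec, vol_dim = cfg$vol_dim))
    vol <- ph$volume
    ph$volume <- NULL  # release the raw render once the stages copy it
    times <- frame_times(vol)
    bundle$truth <- ph$truth
    # the sub-stages rebind `vol` one at a time so at most two full-volume
    # copies are ever alive
    vol <- stage("preprocess", subtract_temporal_background(
      vol, cfg$background_box %||% default_background_box(vol),
      offset = cfg$background_offset))
    reg <- stage("preprocess", register_recursive(
      vol, reference_index = cfg$reference_index,
      fill = cfg$background_offset))
    bundle$transforms <- reg$transforms
    bundle$transforms_um <- lapply(reg$transforms,
                                   function(s) s * vol$spacing)
    vol <- reg$volume
    reg$volume <- NULL
    ali <- stage("preprocess", align_by_mask_com(
      vol, threshold = cfg$mask_threshold,
      rotation_angles = cfg$rotation_angles %||% ph$landmarks$rotation_angles,
      fill = cfg$background_offset))
    bundle$alignment <- ali$alignment
    vol <- ali$volume
    ali$volume <- NULL
    vol <- stage("preprocess", resample_isotropic(vol, cfg$z_factor))
    if (cfg$subsample_factor > 1) {
      vol <- stage("preprocess", subsample_xy(vol, cfg$subsample_factor))
    }
    kymo <- stage("loi", {
      lm <- interpolate_landmarks(ph$landmarks, times)
      # carry the landmarks through registration + alignment translations
      shift_um <- bundle$alignment$translation_um
      for (nm in c("origin", "left_distal", "right_distal")) {
        m <- lm[[nm]]
        for (j in seq_along(times)) {
          m[j, ] <- m[j, ] + bundle$transforms_um[[j]] + shift_um
        }
        lm[[nm]] <- m
      }
      bundle$landmarks <- lm
      com <- volume_center(vol)  # mask COM sits at the center after alignment
      paths <- lapply(c("left_distal", "right_distal"), function(nm) {
        ip <- locate_intermediate_point(vol, com, lm$origin, lm[[nm]])
        lapply(seq_along(times), function(j) {
          build_surface_path(lm$origin[j, ], ip$points[j, ], lm[[nm]][j, ],
                             n_segments = cfg$n_segments)
        })
      })
      bundle$left_paths <- paths[[1]]
      bundle$right_paths <- paths[[2]]
      sample_surface_kymograph(vol, paths[[1]], paths[[2]],
                               smoothing_sigma_px = cfg$surface_sigma_px,
                               sphere_diameter_px = cfg$sphere_diameter_px,
                               fill = cfg$fill_value)
    })
    if (isTRUE(cfg$keep_volume)) bundle$volume <- vol
    rm(vol)
  } else {
    sk <- stage("synth", generate_phantom_kymograph(
      spec, fill = cfg$fill_value, spatial_pixel = cfg$spatial_pixel))
    kymo <- sk$kymo
    bundle$truth <- sk$truth
  }
  bundle$kymo <- kymo
  bundle$phase <- stage("spectral", make_phase_kymograph(
    kymo, onset_frame = cfg$onset_frame,
    spatial_sigma_px = cfg$spatial_sigma_px,
    cutoff_period = cfg$cutoff_period,
    period_grid = default_period_grid(cfg$n_periods, cfg$period_range)))
  bundle$stats <- stage("wavestats", wave_stats(
    bundle$phase, distal_crop_px = cfg$distal_crop_px, side = cfg$side))
  bundle$period_gradient <- stage("wavestats", sample_period_gradient(
    kymo, onset_frame = cfg$onset_frame, window = cfg$period_window,
    distal_shift_px = cfg$distal_shift_px, corridor_px = cfg$corridor_px,
    side = cfg$side, cutoff_period = cfg$cutoff_period,
    period_grid = default_period_grid(cfg$n_periods, cfg$period_range)))
  if (isTRUE(cfg$flow)) {
    bundle$flow <- stage("flow", {
      tk <- generate_phantom_tracks(spec, n_tracks = cfg$n_tracks)
      tracks <- align_track_time(tk$tracks, spec$pulse_peak_time,
                                 onset_offset = cfg$onset_offset_min)
      # in the phantom, imaging and tracking share coordinates: filter
      # against the analytic line of interest
      ptimes <- (seq_len(spec$n_frames) - 1L) * spec$frame_interval_dt
      paths <- phantom_paths(tk$truth, ptimes,
                             n_segments = min(cfg$n_segments, 10000L))
      sel <- filter_tracks_by_path(tracks, paths$left, ptimes,
                                   radius_um = cfg$track_radius_um,
                                   min_consecutive_min = cfg$track_min_consecutive_min)
      bundle$tracks <- sel
      average_vector_field(sel, paths$left[[1]])
    })
  }
  if (!is.null(cfg$output_dir)) stage("write", write_bundle(bundle, cfg))
  invisible(bundle)
}

# Write every pipeline product with a provenance sidecar.
write_bundle <- function(bundle, cfg) {
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(cfg$output_dir, ...)
  write_kymograph(bundle$kymo, out("kymograph"))
  write_kymograph(bundle$phase, out("phase_kymograph"))
  utils::write.csv(as.data.frame(bundle$stats), out("wave_stats.csv"),
                   row.names = FALSE)
  utils::write.csv(attr(bundle$stats, "summary"), out("wave_stats_summary.csv"),
                   row.names = FALSE)
  pg <- bundle$period_gradient
  utils::write.csv(rbind(cbind(region = "proximal", pg$proximal),
                         cbind(region = "distal", pg$distal)),
                   out("period_samples.csv"), row.names = FALSE)
  utils::write.csv(pg$summary, out("period_summary.csv"), row.names = FALSE)
  if (!is.null(bundle$flow)) {
    utils::write.csv(as.data.frame(bundle$flow), out("vector_field.csv"),
                     row.names = FALSE)
  }
  prov <- unclass(cfg)
  prov$phantom_spec <- unclass(cfg$phantom_spec)
  prov$output_dir <- NULL
  jsonlite::write_json(
    list(package = "wavekymo",
         version = as.character(utils::packageVersion("wavekymo")),
         config = prov),
    out("provenance.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE,
    null = "null")
  invisible(cfg$output_dir)
}
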