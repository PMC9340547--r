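# File formats: kymographs and tracks as CSV with JSON sidecars, volumes as
# multi-page TIFF (file per timepoint), ground truth / provenance as JSON.

#' Write a kymograph as CSV plus JSON sidecar
#'
#' The matrix goes to `<path>.csv` (no headers, rows = spatial samples) and
#' the metadata (spatial pixel, dt, midline row, fill, start time, phase
#' flag) to `<path>.json`; the validity mask is implied by the fill value
#' for intensity kymographs and by `NA` for phase kymographs.
#'
#' @param km a [kymograph()] or phase kymograph.
#' @param path output path without extension.
#' @return `path`, invisibly.
#' @export
write_kymograph <- function(km, path) {
  is_phase <- inherits(km, "phase_kymograph")
  m <- km$mat
  if (is_phase) m[!km$valid] <- NA_real_
  utils::write.table(m, paste0(path, ".csv"), sep = ",", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(
    kind = if (is_phase) "phase" else "intensity",
    spatial_pixel_um = km$spatial_pixel, dt_min = km$dt,
    midline_row = km$midline_row, fill = km$fill %||% NA,
    start_time_min = km$start_time,
    onset_frame = if (is_phase) km$onset_frame else NA
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a kymograph written by [write_kymograph()]
#'
#' @param path path without extension.
#' @return a [kymograph()] (intensity) or a `phase_kymograph`-shaped list.
#' @export
read_kymograph <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(utils::read.table(paste0(path, ".csv"), sep = ","))
  dimnames(m) <- NULL
  if (identical(meta$kind, "phase")) {
    valid <- !is.na(m)
    structure(
      list(mat = m, valid = valid, onset_frame = meta$onset_frame,
           spatial_pixel = meta$spatial_pixel_um, dt = meta$dt_min,
           midline_row = meta$midline_row, start_time = meta$start_time_min),
      class = "phase_kymograph")
  } else {
    kymograph(m, spatial_pixel = meta$spatial_pixel_um, dt = meta$dt_min,
              midline_row = meta$midline_row, valid = m != meta$fill,
              fill = meta$fill, start_time = meta$start_time_min)
  }
}

#' Write a volume series as per-frame multi-page TIFFs
#'
#' One 16-bit multi-page TIFF per timepoint (pages = z-slices), named
#' `frame_0000.tif`, ..., plus an `index.json` manifest with spacing, frame
#' interval and intensity scaling.
#'
#' @param vol a [volume_series()].
#' @param dir output directory (created if missing).
#' @param max_count intensity mapped to the 16-bit maximum (default 65535).
#' @return the manifest path, invisibly.
#' @export
write_volume_tiff <- function(vol, dir, max_count = 65535) {
  stopifnot(inherits(vol, "volume_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(vol$frames))
  for (j in seq_along(vol$frames)) {
    f <- vol$frames[[j]]
    pages <- lapply(seq_len(dim(f)[1]), function(z) {
      pmin(pmax(f[z, , ] / max_count, 0), 1)
    })
    files[j] <- sprintf("frame_%04d.tif", j - 1L)
    tiff::writeTIFF(pages, file.path(dir, files[j]), bits.per.sample = 16L)
  }
  manifest <- list(files = files, spacing_um = vol$spacing, dt_min = vol$dt,
                   start_time_min = vol$start_time, max_count = max_count)
  mp <- file.path(dir, "index.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mp)
}

#' Read a volume series written by [write_volume_tiff()]
#'
#' @param dir directory holding `index.json` and the per-frame TIFFs.
#' @return a [volume_series()].
#' @export
read_volume_tiff <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "index.json"),
                                  simplifyVector = TRUE)
  frames <- lapply(manifest$files, function(fn) {
    pages <- tiff::readTIFF(file.path(dir, fn), all = TRUE)
    a <- array(0, dim = c(length(pages), dim(pages[[1]])))
    for (z in seq_along(pages)) a[z, , ] <- pages[[z]] * manifest$max_count
    a
  })
  volume_series(frames, spacing = manifest$spacing_um, dt = manifest$dt_min,
                start_time = manifest$start_time_min)
}

#' Write cell tracks as CSV
#'
#' @param tracks track data.frame (columns `track_id`, `t_min`, `x_um`,
#'   `y_um`, `z_um`).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  validate_tracks(tracks)
  utils::write.csv(tracks[, c("track_id", "t_min", "x_um", "y_um", "z_um")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a cell-track CSV
#'
#' @param path CSV path with header `track_id,t_min,x_um,y_um,z_um`.
#' @return validated track data.frame.
#' @export
read_tracks <- function(path) {
  validate_tracks(utils::read.csv(path))
}

#' Write a landmark set as CSV
#'
#' Long format: one row per keyframe and landmark with columns
#' `t_min`, `landmark`, `z_um`, `y_um`, `x_um`; rotation angles go into the
#' JSON sidecar `<path>.json`.
#'
#' @param lm a [landmark_set()].
#' @param path output path without extension.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(lm, path) {
  stopifnot(inherits(lm, "landmark_set"))
  rows <- do.call(rbind, lapply(c("origin", "left_distal", "right_distal"),
                                function(nm) {
    data.frame(t_min = lm$times, landmark = nm, z_um = lm[[nm]][, 1],
               y_um = lm[[nm]][, 2], x_um = lm[[nm]][, 3])
  }))
  utils::write.csv(rows, paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(list(rotation_angles_deg = lm$rotation_angles),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a landmark set written by [write_landmarks()]
#'
#' @param path path without extension.
#' @return a [landmark_set()].
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(paste0(path, ".csv"))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  get <- function(nm) {
    sub <- df[df$landmark == nm, , drop = FALSE]
    sub <- sub[order(sub$t_min), , drop = FALSE]
    unname(as.matrix(sub[, c("z_um", "y_um", "x_um")]))
  }
  times <- sort(unique(df$t_min))
  landmark_set(times, get("origin"), get("left_distal"), get("right_distal"),
               rotation_angles = meta$rotation_angles_deg)
}

#' Write phantom ground truth as a JSON sidecar
#'
#' Serializes the generating parameters (from which the analytic phase,
#' period and wave-number functions are fully reconstructible) together
#' with tabulated ground-truth values per frame time: arc length, analytic
#' `q(t)` and the proximal/distal periods.
#'
#' @param truth a `phantom_truth`.
#' @param path output JSON path.
#' @param times frame times (min) at which to tabulate the analytic values.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path,
                               times = (seq_len(truth$spec$n_frames) - 1L) *
                                 truth$spec$frame_interval_dt) {
  stopifnot(inherits(truth, "phantom_truth"))
  obj <- list(
    parameters = unclass(truth$spec),
    track_velocities_um_per_min = truth$track_velocities,
    per_frame = data.frame(
      t_min = times,
      arc_length_um = truth$arc_length(times),
      q = truth$q(times),
      proximal_period_min = truth$period(0, times),
      distal_period_min = truth$period(truth$arc_length(times), times)
    )
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", dataframe = "columns")
  invisible(path)
}

#' Write a wavelet ridge as CSV
#'
#' @param ridge a [extract_ridge()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ridge <- function(ridge, path) {
  utils::write.csv(as.data.frame(ridge), path, row.names = FALSE)
  invisible(path)
}

#' Write a wavelet spectrum as delimited matrices with a JSON sidecar
#'
#' Real and imaginary coefficient parts go to `<path>_re.csv` and
#' `<path>_im.csv` (rows = grid periods, columns = timepoints); the period
#' grid and sampling parameters go to `<path>.json`.
#'
#' @param spec a [morlet_spectrum()] result.
#' @param path output path without extension.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "wavelet_spectrum"))
  utils::write.table(Re(spec$coef), paste0(path, "_re.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(Im(spec$coef), paste0(path, "_im.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(period_grid_min = spec$period_grid, dt_min = spec$dt,
         coi_scale = spec$coi_scale),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
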