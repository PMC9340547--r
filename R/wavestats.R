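#' Wave number q per timepoint
#'
#' For each column of a phase kymograph, the phases of one side are spatially
#' unwrapped from the midline outward over the valid cells, the distal-most
#' rows are cropped off, and the absolute phase difference between the distal
#' end and the midline is divided by `2 * pi`. `q = 1` means one full wave
#' spans the domain. Columns with fewer than two valid cells after cropping
#' yield `NA`.
#'
#' @param pk a [make_phase_kymograph()].
#' @param distal_crop_px rows cropped at the distal end (default 20, about
#'   41.8 um), matching the period measurements.
#' @param side kymograph side used, `"left"` (top half, default) or
#'   `"right"`.
#' @return data.frame with columns `time` (min, onset-relative), `q` and
#'   `n_rows` (valid rows used after cropping).
#' @export
compute_wave_number <- function(pk, distal_crop_px = 20L,
                                side = c("left", "right")) {
  stopifnot(inherits(pk, "phase_kymograph"))
  side <- match.arg(side)
  rows <- side_rows(pk, side)
  n_t <- ncol(pk$mat)
  q <- rep(NA_real_, n_t)
  n_used <- integer(n_t)
  for (j in seq_len(n_t)) {
    v <- pk$valid[rows, j]
    run <- cumprod(v) > 0           # contiguous valid run from the midline
    phi <- pk$mat[rows[run], j]
    n_keep <- length(phi) - distal_crop_px
    if (n_keep >= 2L) {
      phi <- unwrap_phase(phi[seq_len(n_keep)])
      q[j] <- abs(phi[n_keep] - phi[1]) / (2 * pi)
      n_used[j] <- n_keep
    }
  }
  data.frame(time = (seq_len(n_t) - 1L) * pk$dt, q = q, n_rows = n_used)
}

#' Mesoderm length per timepoint
#'
#' The length of the cropped kymograph column — the spline length on the
#' mesoderm surface minus the distal crop — used to normalize the wave
#' number. Accepts a phase kymograph (valid rows times the spatial pixel) or
#' a list of per-frame [build_surface_path()]s (tabulated arc length).
#'
#' @param x a `phase_kymograph`, a [kymograph()], or a list of
#'   `surface_path`s (one per frame).
#' @param distal_crop_px rows cropped at the distal end (default 20).
#' @param side kymograph side, as in [compute_wave_number()].
#' @param spatial_pixel pixel size in um; required for a path list, taken
#'   from the object otherwise.
#' @return data.frame with columns `time` (min; `NA` for a path list without
#'   times) and `L_um`.
#' @export
mesoderm_length <- function(x, distal_crop_px = 20L,
                            side = c("left", "right"),
                            spatial_pixel = NULL) {
  side <- match.arg(side)
  if (inherits(x, "phase_kymograph") || inherits(x, "kymograph")) {
    rows <- side_rows(x, side)
    px <- x$spatial_pixel
    n_t <- ncol(x$mat)
    l <- vapply(seq_len(n_t), function(j) {
      v <- x$valid[rows, j]
      n <- sum(cumprod(v) > 0) - distal_crop_px
      if (n >= 1L) n * px else NA_real_
    }, numeric(1))
    return(data.frame(time = (seq_len(n_t) - 1L) * x$dt, L_um = l))
  }
  if (is.list(x) && all(vapply(x, inherits, logical(1), "surface_path"))) {
    if (is.null(spatial_pixel)) {
      stop("spatial_pixel is required when measuring from surface paths")
    }
    l <- vapply(x, function(p) {
      n <- floor(p$total_length / spatial_pixel) + 1L - distal_crop_px
      if (n >= 1L) n * spatial_pixel else NA_real_
    }, numeric(1))
    return(data.frame(time = NA_real_, L_um = l))
  }
  stop("missing path or kymograph: x must be a (phase) kymograph or a list of surface_path objects")
}

#' Phase-gradient slope
#'
#' Divides the wave number by the mesoderm length at each timepoint — the
#' linear estimate of the phase gradient, in waves per micrometer.
#'
#' @param q per-time wave numbers (vector, or the data.frame from
#'   [compute_wave_number()]).
#' @param L per-time mesoderm lengths in um (vector, or the data.frame from
#'   [mesoderm_length()]).
#' @return numeric vector of slopes; `NA` where either input is undefined or
#'   `L` is zero.
#' @export
compute_phase_gradient_slope <- function(q, L) {
  if (is.data.frame(q)) q <- q$q
  if (is.data.frame(L)) L <- L$L_um
  if (length(q) != length(L)) stop("q and L must be aligned in time")
  out <- q / L
  out[!is.finite(out)] <- NA_real_
  out
}

#' Per-time wave statistics of a phase kymograph
#'
#' Convenience wrapper computing wave number, mesoderm length and
#' phase-gradient slope on one side of a phase kymograph, with median/IQR
#' summaries.
#'
#' @inheritParams compute_wave_number
#' @return object of class `wave_stats`: data.frame with columns `time`,
#'   `q`, `L_um`, `slope`; summaries in `attr(, "summary")`.
#' @export
wave_stats <- function(pk, distal_crop_px = 20L, side = c("left", "right")) {
  side <- match.arg(side)
  qd <- compute_wave_number(pk, distal_crop_px, side)
  ld <- mesoderm_length(pk, distal_crop_px, side)
  out <- data.frame(time = qd$time, q = qd$q, L_um = ld$L_um,
                    slope = compute_phase_gradient_slope(qd, ld))
  summ <- do.call(rbind, lapply(c("q", "L_um", "slope"), function(v) {
    data.frame(quantity = v, median = stats::median(out[[v]], na.rm = TRUE),
               iqr = stats::IQR(out[[v]], na.rm = TRUE))
  }))
  attr(out, "summary") <- summ
  attr(out, "side") <- side
  class(out) <- c("wave_stats", "data.frame")
  out
}

#' @export
print.wave_stats <- function(x, ...) {
  cat(sprintf("<wave_stats> %d timepoints, side: %s\n", nrow(x),
              attr(x, "side")))
  print(attr(x, "summary"), row.names = FALSE)
  invisible(x)
}

#' Proximal and distal period-gradient sampling
#'
#' Reads instantaneous periods in two regions of an intensity kymograph: the
#' proximal series follows the midline, the distal series follows the
#' kymograph boundary contour shifted towards the midline (so it stays inside
#' the oscillatory domain and moves with tissue expansion). Intensities are
#' averaged in a corridor around each path, detrended, wavelet-transformed
#' and read along the power-maximum ridge; period values within the sampling
#' window after wave onset are collected and reduced to median and IQR.
#'
#' @param kymo a [kymograph()] of intensities.
#' @param onset_frame column index of wave onset.
#' @param window sampling window in minutes after onset (default
#'   `c(120, 360)`, i.e. 2-6 h; 24 samples per region at 10 min frames).
#' @param distal_shift_px rows the distal contour is shifted from the
#'   boundary towards the midline (default 20, about 41.8 um).
#' @param corridor_px corridor width in rows for intensity averaging
#'   (default 8, about 16.7 um).
#' @param side kymograph side used (default `"left"`, the top half).
#' @param cutoff_period,period_grid spectral parameters, see
#'   [sinc_detrend()] and [morlet_spectrum()].
#' @return object of class `period_gradient`: list with `proximal` and
#'   `distal` sample data.frames (`time`, `period`), a `summary` data.frame
#'   (region, median, iqr, n) and the parameters used.
#' @export
sample_period_gradient <- function(kymo, onset_frame, window = c(120, 360),
                                   distal_shift_px = 20L, corridor_px = 8L,
                                   side = c("left", "right"),
                                   cutoff_period = 220,
                                   period_grid = default_period_grid()) {
  stopifnot(inherits(kymo, "kymograph"))
  side <- match.arg(side)
  cols <- onset_frame:ncol(kymo$mat)
  n_t <- length(cols)
  t_rel <- (seq_len(n_t) - 1L) * kymo$dt
  if (window[2] > max(t_rel)) {
    stop(sprintf("sampling window ends at %g min but the recording covers only %g min after onset",
                 window[2], max(t_rel)))
  }
  rows <- side_rows(kymo, side)
  dir <- if (side == "left") -1L else 1L
  corridor_offsets <- seq_len(corridor_px) - 1L - floor((corridor_px - 1L) / 2)
  corridor_mean <- function(center_rows) {
    vapply(seq_len(n_t), function(j) {
      rr <- center_rows[j] + corridor_offsets
      rr <- rr[rr >= 1L & rr <= nrow(kymo$mat)]
      rr <- rr[kymo$valid[rr, cols[j]]]
      if (length(rr) == 0L) return(NA_real_)
      mean(kymo$mat[rr, cols[j]])
    }, numeric(1))
  }
  prox_series <- corridor_mean(rep(kymo$midline_row, n_t))
  boundary <- vapply(seq_len(n_t), function(j) {
    v <- kymo$valid[rows, cols[j]]
    n <- sum(cumprod(v) > 0)
    rows[max(n, 1L)]
  }, integer(1))
  dist_series <- corridor_mean(boundary - dir * distal_shift_px)
  if (anyNA(prox_series) || anyNA(dist_series)) {
    stop("region series leave the valid kymograph domain; reduce distal_shift_px or corridor_px")
  }
  plan <- morlet_fft_plan(n_t, period_grid, kymo$dt)
  in_win <- t_rel >= window[1] & t_rel < window[2]
  read_region <- function(series) {
    rd <- series_ridge(series, dt = kymo$dt, cutoff_period = cutoff_period,
                       period_grid = period_grid, plan = plan)
    data.frame(time = t_rel[in_win], period = rd$period[in_win])
  }
  prox <- read_region(prox_series)
  dist <- read_region(dist_series)
  summ <- rbind(
    data.frame(region = "proximal", median = stats::median(prox$period),
               iqr = stats::IQR(prox$period), n = nrow(prox)),
    data.frame(region = "distal", median = stats::median(dist$period),
               iqr = stats::IQR(dist$period), n = nrow(dist))
  )
  structure(
    list(proximal = prox, distal = dist, summary = summ,
         params = list(onset_frame = onset_frame, window = window,
                       distal_shift_px = distal_shift_px,
                       corridor_px = corridor_px, side = side)),
    class = "period_gradient"
  )
}

#' @export
print.period_gradient <- function(x, ...) {
  cat("<period_gradient>\n")
  print(x$summary, row.names = FALSE)
  cat(sprintf("  gradient (distal - proximal medians): %.2f min\n",
              x$summary$median[2] - x$summary$median[1]))
  invisible(x)
}
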