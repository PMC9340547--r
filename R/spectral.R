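#' Sinc (low-pass) detrending
#'
#' Estimates the slow trend of a time series with a Blackman-windowed sinc
#' low-pass filter at the given cut-off period and subtracts it, leaving the
#' oscillatory band untouched. Boundaries are handled by reflect padding;
#' the kernel half-width is twice the cut-off period (narrow enough for
#' typical recordings, wide enough that the filter's transition band leaves
#' the 100-220 min analysis band essentially untouched).
#'
#' @param series numeric time series sampled at `dt`.
#' @param cutoff_period cut-off period in minutes (default 220); frequency
#'   components slower than this are treated as trend.
#' @param dt sampling interval in minutes.
#' @return the detrended series (same length).
#' @export
sinc_detrend <- function(series, cutoff_period = 220, dt,
                         halfwidth_factor = 2) {
  if (dt <= 0) stop("dt must be > 0")
  n <- length(series)
  if (n < 2L) stop("series must have length >= 2")
  half <- as.integer(ceiling(halfwidth_factor * cutoff_period / dt))
  if (half > n - 1L) {
    stop(sprintf(
      "series of length %d is shorter than the sinc kernel half-width (%d samples); no padding possible",
      n, half))
  }
  series - sinc_trend(series, cutoff_period, dt, half)
}

sinc_kernel <- function(cutoff_period, dt, half) {
  fc <- dt / cutoff_period            # cut-off in cycles per sample
  j <- -half:half
  h <- 2 * fc * sinc(2 * fc * j)
  m <- length(j)
  w <- 0.42 - 0.5 * cos(2 * pi * (j + half) / (m - 1)) +
    0.08 * cos(4 * pi * (j + half) / (m - 1))
  h <- h * w
  h / sum(h)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

sinc_trend <- function(series, cutoff_period, dt, half) {
  convolve_reflect(series, sinc_kernel(cutoff_period, dt, half))
}

#' Default wavelet period grid
#'
#' 600 periods spanning 100 to 220 minutes, the grid used for phase and
#' period extraction.
#'
#' @param n number of periods.
#' @param range period range in minutes.
#' @return numeric vector of periods.
#' @export
default_period_grid <- function(n = 600L, range = c(100, 220)) {
  seq(range[1], range[2], length.out = n)
}

#' Complex Morlet wavelet spectrum
#'
#' Continuous wavelet transform of a (detrended) time series with complex
#' Morlet wavelets of central angular frequency `2 * pi`, so that the
#' wavelet scale equals the Fourier period and a sinusoid at a grid period
#' produces its power maximum at that grid period. Coefficients are
#' normalized so a unit-amplitude sinusoid yields ridge power 1 away from
#' the series edges; the phase convention is `0` at an oscillation maximum
#' (cosine convention).
#'
#' @param series numeric time series sampled at `dt`.
#' @param period_grid strictly increasing periods in minutes (default
#'   [default_period_grid()]); all must exceed the Nyquist period `2 * dt`.
#' @param dt sampling interval in minutes.
#' @param plan optional precomputed kernel plan from `morlet_fft_plan()` for
#'   repeated transforms of equal-length series (internal speed-up).
#' @return object of class `wavelet_spectrum`: complex coefficient matrix
#'   `coef` (periods x time), `power`, the `period_grid`, `dt` and the
#'   edge-effect margin `coi_scale` (edge effects are expected within
#'   `coi_scale` times the period of the nearer series end; 2 for this
#'   wavelet, whose Gaussian envelope has standard deviation one period).
#' @export
morlet_spectrum <- function(series, period_grid = default_period_grid(), dt,
                            plan = NULL) {
  n <- length(series)
  if (is.null(plan)) plan <- morlet_fft_plan(n, period_grid, dt)
  stopifnot(plan$n == n)
  m <- plan$m
  xpad <- c(as.numeric(series), rep(0, m - n))
  xf <- stats::fft(xpad)
  prod <- plan$kf * matrix(xf, nrow = m, ncol = length(period_grid))
  conv <- stats::mvfft(prod, inverse = TRUE) / m
  coef <- t(conv[seq_len(n), , drop = FALSE])
  # unit cosine at a grid period -> |coef| = pi^(-1/4) * sqrt(2*pi) / 2
  coef <- coef * (2 * pi^0.25 / sqrt(2 * pi))
  t_edge <- pmin(seq_len(n) - 1L, n - seq_len(n)) * dt
  structure(
    list(coef = coef, power = Mod(coef)^2, period_grid = period_grid,
         dt = dt, coi_scale = 2, time_from_edge = t_edge),
    class = "wavelet_spectrum"
  )
}

# Precompute the wrapped, FFT-transformed Morlet kernels for series of
# length n on a given period grid.
morlet_fft_plan <- function(n, period_grid, dt) {
  if (dt <= 0) stop("dt must be > 0")
  if (any(diff(period_grid) <= 0)) stop("period_grid must be strictly increasing")
  if (min(period_grid) <= 2 * dt) {
    stop(sprintf("grid periods must exceed the Nyquist period 2*dt = %g min",
                 2 * dt))
  }
  np <- length(period_grid)
  half_max <- ceiling(4 * max(period_grid) / dt)
  m <- stats::nextn(n + 2L * half_max, 2L)
  kern <- matrix(0 + 0i, nrow = m, ncol = np)
  for (p in seq_len(np)) {
    s <- period_grid[p]
    half <- ceiling(4 * s / dt)
    j <- -half:half
    u <- j * dt / s
    psi <- pi^(-0.25) * exp(2i * pi * u) * exp(-u^2 / 2)
    idx <- (j %% m) + 1L
    kern[idx, p] <- kern[idx, p] + psi * dt / s
  }
  list(n = n, m = m, kf = stats::mvfft(kern), period_grid = period_grid,
       dt = dt)
}

#' @export
print.wavelet_spectrum <- function(x, ...) {
  cat(sprintf("<wavelet_spectrum> %d periods (%.4g-%.4g min) x %d timepoints, dt %g min\n",
              length(x$period_grid), min(x$period_grid), max(x$period_grid),
              ncol(x$coef), x$dt))
  invisible(x)
}

#' Trace the power-maximum ridge of a wavelet spectrum
#'
#' Per timepoint, the grid period with maximal power is selected (ties break
#' toward the smaller period); evaluating the complex transform along this
#' ridge yields instantaneous period, phase and power. Entries with ridge
#' power below the threshold are flagged invalid.
#'
#' @param spec a [morlet_spectrum()].
#' @param power_threshold minimal ridge power for a valid entry (default 0,
#'   i.e. all entries valid).
#' @return object of class `wavelet_ridge`: data.frame with columns `time`
#'   (minutes from the series start), `period`, `phase`, `power`, `valid`.
#' @export
extract_ridge <- function(spec, power_threshold = 0) {
  stopifnot(inherits(spec, "wavelet_spectrum"))
  n <- ncol(spec$coef)
  i <- max.col(t(spec$power), ties.method = "first")
  idx <- cbind(i, seq_len(n))
  period <- spec$period_grid[i]
  cc <- spec$coef[idx]
  ridge <- data.frame(
    time = (seq_len(n) - 1L) * spec$dt,
    period = period,
    phase = Arg(cc),
    power = spec$power[idx],
    valid = spec$power[idx] >= power_threshold
  )
  class(ridge) <- c("wavelet_ridge", "data.frame")
  attr(ridge, "dt") <- spec$dt
  ridge
}

# Full per-series chain: detrend -> wavelet -> ridge.
series_ridge <- function(series, dt, cutoff_period = 220,
                         period_grid = default_period_grid(),
                         power_threshold = 0, plan = NULL) {
  det <- sinc_detrend(series, cutoff_period = cutoff_period, dt = dt)
  extract_ridge(morlet_spectrum(det, period_grid = period_grid, dt = dt,
                                plan = plan),
                power_threshold = power_threshold)
}

#' Phase kymograph
#'
#' Crops the frames preceding the (manually determined) wave-onset frame,
#' smooths the intensity kymograph with a Gaussian along the spatial
#' dimension, then runs every row through sinc detrending, the Morlet
#' wavelet transform and ridge tracing; re-stacking the per-row ridge phases
#' produces the phase kymograph. Ridge periods and powers are kept alongside
#' for period readouts.
#'
#' @param kymo a [kymograph()] of intensities.
#' @param onset_frame column index of the first oscillatory frame; earlier
#'   columns are cropped.
#' @param spatial_sigma_px Gaussian sigma along the spatial axis in pixels
#'   (default 5, about 10.4 um).
#' @param cutoff_period sinc detrending cut-off period in minutes.
#' @param period_grid wavelet period grid in minutes.
#' @param power_threshold minimal ridge power for a valid phase.
#' @return object of class `phase_kymograph`: wrapped-phase matrix `mat`
#'   (radians), `period` and `power` matrices, validity mask, `onset_frame`,
#'   and the source `spatial_pixel`, `dt`, `midline_row`.
#' @export
make_phase_kymograph <- function(kymo, onset_frame, spatial_sigma_px = 5,
                                 cutoff_period = 220,
                                 period_grid = default_period_grid(),
                                 power_threshold = 0) {
  stopifnot(inherits(kymo, "kymograph"))
  n_col <- ncol(kymo$mat)
  if (onset_frame < 1L || onset_frame > n_col) {
    stop("onset_frame must be a column index of the kymograph")
  }
  cols <- onset_frame:n_col
  m <- kymo$mat[, cols, drop = FALSE]
  valid <- kymo$valid[, cols, drop = FALSE]
  if (spatial_sigma_px > 0) {
    kern <- gaussian_kernel(spatial_sigma_px)
    m <- apply(m, 2L, convolve_reflect, kernel = kern)
  }
  n_t <- ncol(m)
  half <- as.integer(ceiling(2 * cutoff_period / kymo$dt))
  if (half > n_t - 1L) {
    stop(sprintf(
      "only %d frames remain after cropping at onset %d; the detrending filter needs more than %d",
      n_t, onset_frame, half))
  }
  phase <- period <- power <- matrix(NA_real_, nrow(m), n_t)
  plan <- morlet_fft_plan(n_t, period_grid, kymo$dt)
  for (r in seq_len(nrow(m))) {
    rd <- series_ridge(m[r, ], dt = kymo$dt, cutoff_period = cutoff_period,
                       period_grid = period_grid,
                       power_threshold = power_threshold, plan = plan)
    phase[r, ] <- rd$phase
    period[r, ] <- rd$period
    power[r, ] <- rd$power
    valid[r, ] <- valid[r, ] & rd$valid
  }
  structure(
    list(mat = phase, period = period, power = power, valid = valid,
         onset_frame = as.integer(onset_frame),
         spatial_pixel = kymo$spatial_pixel, dt = kymo$dt,
         midline_row = kymo$midline_row,
         start_time = kymo$start_time + (onset_frame - 1L) * kymo$dt),
    class = "phase_kymograph"
  )
}

#' @export
print.phase_kymograph <- function(x, ...) {
  cat(sprintf("<phase_kymograph> %d rows x %d timepoints (onset frame %d cropped)\n",
              nrow(x$mat), ncol(x$mat), x$onset_frame))
  cat(sprintf("  spatial pixel %.4g um, dt %g min, %.1f%% valid\n",
              x$spatial_pixel, x$dt, 100 * mean(x$valid)))
  invisible(x)
}
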