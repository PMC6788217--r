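#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities with the standard parameterization:
#' response peak delay 6 s, undershoot delay 16 s, both dispersions 1 s,
#' peak-to-undershoot ratio 6, evaluated on `[0, 32]` s and normalized to a
#' peak of 1. With these parameters the mode of the positive lobe lies at
#' `(shape - 1) * scale = 5` s.
#'
#' @param dt sample spacing in seconds, `0 < dt <= 1`.
#' @param length_s kernel support in seconds.
#' @return object of class `hrf_kernel`: `values`, `times`, `dt`, `params`.
#' @export
canonical_hrf <- function(dt = 1, length_s = 32) {
  stopifnot(dt > 0, dt <= 1)
  t <- seq(0, length_s, by = dt)
  params <- list(peak_delay = 6, undershoot_delay = 16, dispersion = 1,
                 u_dispersion = 1, ratio = 6, length_s = length_s)
  h <- stats::dgamma(t, shape = params$peak_delay / params$dispersion,
                     scale = params$dispersion) -
    stats::dgamma(t, shape = params$undershoot_delay / params$u_dispersion,
                  scale = params$u_dispersion) / params$ratio
  h <- h / max(h)
  structure(list(values = h, times = t, dt = dt, params = params),
            class = "hrf_kernel")
}

#' Occipital sensor-level band power regressor
#'
#' Averages the named channels' signals into one trace, then computes its
#' short-time Fourier band power (2 s Hamming window, 50% overlap: one
#' sample per second), reproducing the classic occipital alpha regressor.
#'
#' @param clean_rec a cleaned `sensor_recording`.
#' @param channel_names channels to average (must exist; non-empty).
#' @param band band name (default `"alpha"`).
#' @return numeric band-power time-course at 1 Hz (length
#'   `floor(duration) - 1`).
#' @export
occipital_power_regressor <- function(clean_rec, channel_names,
                                      band = "alpha") {
  if (length(channel_names) == 0) stop("channel list is empty")
  idx <- match(channel_names, clean_rec$labels)
  if (anyNA(idx)) stop("unknown channel(s): ",
                       paste(channel_names[is.na(idx)], collapse = ", "))
  avg <- colMeans(clean_rec$data[idx, , drop = FALSE])
  sp <- stft_power(avg, clean_rec$fs)
  e <- band_edges(band)
  band_mean_power(sp, e[1], e[2])
}

#' Convolve a power time-course with an HRF kernel
#'
#' Causal linear convolution truncated to the input length; the first
#' `length_s` seconds are flagged as burn-in (attribute `burn_in_s`) so
#' downstream correlation can exclude convolution edge effects.
#'
#' @param timecourse numeric series sampled at the kernel's rate.
#' @param kernel an `hrf_kernel` (its `dt` must match the series spacing).
#' @return convolved series, same length, with attribute `burn_in_s`.
#' @export
hrf_convolve <- function(timecourse, kernel) {
  n <- length(timecourse)
  out <- stats::convolve(c(timecourse, numeric(length(kernel$values))),
                         rev(kernel$values), type = "open")
  out <- out[seq_len(n)]
  attr(out, "burn_in_s") <- kernel$params$length_s
  out
}

#' Upsample a BOLD volume series to a 1 Hz grid
#'
#' Per-voxel linear interpolation from the TR grid `0, tr, 2 tr, ...` onto
#' the 1 Hz grid spanning the same extent, matching the EEG power temporal
#' resolution.
#'
#' @param vol a `volume_series`.
#' @param to_rate target rate in Hz (default 1).
#' @return a `volume_series` at the target rate (its `tr` becomes
#'   `1/to_rate`).
#' @export
upsample_bold <- function(vol, to_rate = 1) {
  n <- ncol(vol$values)
  t_old <- (seq_len(n) - 1) * vol$tr
  t_new <- seq(0, t_old[n], by = 1 / to_rate)
  vals <- t(apply(vol$values, 1, function(x)
    stats::approx(t_old, x, xout = t_new)$y))
  structure(list(values = vals, tr = 1 / to_rate, grid_ref = vol$grid_ref),
            class = "volume_series")
}

#' Voxelwise correlation of an EEG-derived regressor with BOLD
#'
#' Truncates the regressor and the 1 Hz BOLD series to their common
#' length, drops the initial `burn_in_s` seconds, computes the Pearson
#' correlation per voxel, clips `|r|` below 1, and applies the Fisher
#' r-to-z transform.
#'
#' @param regressor numeric series at 1 Hz (e.g. HRF-convolved power).
#' @param bold_1hz a `volume_series` at 1 Hz (see [upsample_bold()]).
#' @param burn_in_s initial seconds to discard (default 32).
#' @return object of class `zmap`: `z` per voxel, `r`, `n_used`, `band`
#'   (NA; set by callers), `regressor_kind`.
#' @export
correlate_voxelwise <- function(regressor, bold_1hz, burn_in_s = 32) {
  n <- min(length(regressor), ncol(bold_1hz$values))
  keep <- seq_len(n) > burn_in_s
  if (sum(keep) < 30)
    stop("fewer than 30 overlapping samples after burn-in")
  x <- regressor[seq_len(n)][keep]
  if (stats::sd(x) == 0) stop("degenerate regressor")
  y <- bold_1hz$values[, seq_len(n), drop = FALSE][, keep, drop = FALSE]
  r <- row_cor(y, x)
  structure(list(z = fisher_z(r), r = r, n_used = sum(keep),
                 band = NA_character_, regressor_kind = NA_character_),
            class = "zmap")
}
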