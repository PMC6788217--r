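#' Remove the MR gradient artifact by average artifact subtraction + OBS
#'
#' Per channel, the recording is epoched on the TR onset markers; each
#' epoch has the sliding average of the `n_avg_epochs` nearest epochs
#' (including itself) subtracted — the average artifact subtraction (AAS)
#' template — and the residual epochs then have their top `n_obs_pcs`
#' principal components fitted and removed per epoch (optimal basis set,
#' OBS), absorbing slow artifact shape changes. Samples outside complete
#' TR epochs are left untouched.
#'
#' @param rec a `sensor_recording` with `tr_markers`.
#' @param n_avg_epochs epochs entering the sliding AAS template.
#' @param n_obs_pcs number of OBS principal components (0 disables OBS).
#' @return list with the cleaned `sensor_recording` and a `report`
#'   (class `cleaning_report`) of per-channel residual variance.
#' @export
remove_gradient_artifact <- function(rec, n_avg_epochs = 20, n_obs_pcs = 3) {
  if (length(rec$tr_markers) == 0) stop("gradient markers required")
  if (length(rec$tr_markers) < 2 * max(n_avg_epochs, 1) &&
      length(rec$tr_markers) < 2)
    stop("too few TR epochs for template estimation")
  out <- rec
  n <- ncol(rec$data)
  marks <- rec$tr_markers
  len <- if (length(marks) > 1) min(diff(marks)) else n - marks[1] + 1
  marks <- marks[marks + len - 1 <= n]
  for (ch in seq_len(nrow(rec$data))) {
    e <- epoch_matrix(rec$data[ch, ], marks, 0, len - 1)
    e_clean <- e - sliding_epoch_mean(e, n_avg_epochs)
    if (n_obs_pcs > 0) e_clean <- obs_subtract(e_clean, n_obs_pcs)
    for (i in seq_along(marks))
      out$data[ch, marks[i]:(marks[i] + len - 1L)] <- e_clean[i, ]
  }
  list(rec = out,
       report = cleaning_report("gradient_aas_obs", rec, out))
}

#' Remove the ballistocardiogram artifact by optimal basis set subtraction
#'
#' The recording is epoched on cardiac R-peak markers in a window from
#' -0.2 s to +0.6 s around each peak (covering the lag of the pulse
#' artifact); per channel, the top `n_obs_pcs` principal components of the
#' epoch matrix are fitted to each epoch by least squares and subtracted.
#' With 0 components the recording is returned unchanged.
#'
#' @param rec a `sensor_recording` with `cardiac_markers` (run
#'   [detect_r_peaks()] first if absent).
#' @param n_obs_pcs number of basis components.
#' @param window_s epoch window around each R peak, seconds.
#' @return list with the cleaned `sensor_recording` and a `report`.
#' @export
remove_bcg_artifact <- function(rec, n_obs_pcs = 3,
                                window_s = c(-0.2, 0.6)) {
  marks <- rec$cardiac_markers
  if (length(marks) == 0) stop("cardiac markers required; run detect_r_peaks")
  fs <- rec$fs
  lo <- round(window_s[1] * fs); hi <- round(window_s[2] * fs) - 1L
  n <- ncol(rec$data)
  marks <- marks[marks + lo >= 1 & marks + hi <= n]
  if (length(marks) < 10) stop("fewer than 10 usable cardiac epochs")
  out <- rec
  if (n_obs_pcs > 0) {
    for (ch in seq_len(nrow(rec$data))) {
      e <- epoch_matrix(rec$data[ch, ], marks, lo, hi)
      e_clean <- obs_subtract(e, n_obs_pcs)
      fix <- e_clean - e
      for (i in seq_along(marks)) {
        idx <- (marks[i] + lo):(marks[i] + hi)
        out$data[ch, idx] <- out$data[ch, idx] + fix[i, ]
      }
    }
  }
  list(rec = out, report = cleaning_report("bcg_obs", rec, out))
}

epoch_matrix <- function(x, marks, lo, hi) {
  idx <- outer(marks + lo, 0:(hi - lo), `+`)
  matrix(x[idx], nrow = length(marks))
}

# sliding mean over up to n_avg nearest epochs (including the current one)
sliding_epoch_mean <- function(e, n_avg) {
  n_ep <- nrow(e)
  n_avg <- min(n_avg, n_ep)
  half <- n_avg %/% 2
  out <- matrix(0, n_ep, ncol(e))
  for (i in seq_len(n_ep)) {
    a <- max(1, i - half); b <- min(n_ep, a + n_avg - 1)
    a <- max(1, b - n_avg + 1)
    out[i, ] <- colMeans(e[a:b, , drop = FALSE])
  }
  out
}

# subtract the per-epoch least-squares fit of the top n principal
# components (time-domain basis) of the epoch matrix
obs_subtract <- function(e, n_pcs) {
  n_pcs <- min(n_pcs, nrow(e) - 1, ncol(e))
  if (n_pcs < 1) return(e)
  sv <- svd(e, nu = 0, nv = n_pcs)
  basis <- sv$v                       # ncol(e) x n_pcs, orthonormal
  e - (e %*% basis) %*% t(basis)
}

cleaning_report <- function(step, before, after) {
  structure(list(step = step,
                 resid_var = apply(before$data - after$data, 1, stats::var),
                 channel_var = apply(after$data, 1, stats::var)),
            class = "cleaning_report")
}

#' Detect R peaks in an ECG trace
#'
#' The trace is band-passed 5-20 Hz, squared, and peaks are picked greedily
#' (largest first) with a 0.5 s refractory period, keeping peaks above 20%
#' of the median accepted peak height.
#'
#' @param ecg numeric single-channel trace (>= 10 s).
#' @param fs sampling rate (Hz).
#' @return integer vector of marker sample indices (possibly empty).
#' @export
detect_r_peaks <- function(ecg, fs) {
  if (length(ecg) < 10 * fs) stop("ECG trace shorter than 10 s")
  bp <- signal::butter(4, c(5, 20) / (fs / 2), type = "pass")
  sq <- signal::filtfilt(bp, as.numeric(ecg))^2
  if (max(sq) <= 0 || stats::sd(sq) == 0) return(integer(0))
  refr <- round(0.5 * fs)
  avail <- rep(TRUE, length(sq))
  peaks <- integer(0)
  thr <- 0.2 * max(sq)
  repeat {
    cand <- which(avail & sq >= thr)
    if (!length(cand)) break
    p <- cand[which.max(sq[cand])]
    peaks <- c(peaks, p)
    avail[max(1, p - refr):min(length(sq), p + refr)] <- FALSE
  }
  sort(peaks)
}

#' Detect channels with poor signal quality
#'
#' Two statistics per channel: (A) the mean absolute Pearson correlation of
#' the 1-80 Hz-filtered channel with every other channel (disconnected or
#' noise-dominated channels decorrelate from the array), and (B) the signal
#' variance in a 200-250 Hz band where brain activity is negligible, so
#' that variance there measures channel noise. A channel is flagged bad if
#' either statistic is an outlier — below (A) or above (B) the median by
#' more than `3 * 1.4826 * MAD` of its cross-channel distribution. When the
#' sampling rate puts 200 Hz above Nyquist the noise band falls back to
#' 0.4-0.5 x Nyquist with a warning.
#'
#' @param rec a `sensor_recording` with >= 8 channels.
#' @param n_mad outlier cut in robust standard deviations.
#' @return list with `bad_flags` (logical per channel) and `report`
#'   data.frame of the statistics and triggering criterion.
#' @export
detect_bad_channels <- function(rec, n_mad = 3) {
  n_ch <- nrow(rec$data)
  if (n_ch < 8) stop("bad-channel detection needs at least 8 channels")
  fs <- rec$fs
  filt <- bandpass_filter(rec, 1, min(80, 0.45 * fs))
  cm <- abs(stats::cor(t(filt$data)))
  diag(cm) <- NA
  mean_corr <- rowMeans(cm, na.rm = TRUE)
  if (fs >= 500) {
    noise_band <- c(200, min(250, 0.499 * fs))
  } else {
    noise_band <- c(0.4, 0.5 - 1e-3) * fs
    warning("noise band 200-250 Hz above Nyquist; using ",
            round(noise_band[1]), "-", round(noise_band[2]), " Hz",
            call. = FALSE)
  }
  bn <- signal::butter(4, noise_band / (fs / 2), type = "pass")
  noise_var <- apply(rec$data, 1,
                     function(x) stats::var(signal::filtfilt(bn, x)))
  lo_out <- function(x) x < stats::median(x) - n_mad * stats::mad(x)
  hi_out <- function(x) x > stats::median(x) + n_mad * stats::mad(x)
  bad_a <- lo_out(mean_corr)
  bad_b <- hi_out(noise_var)
  crit <- ifelse(bad_a & bad_b, "corr+noise",
                 ifelse(bad_a, "corr", ifelse(bad_b, "noise", "")))
  list(bad_flags = bad_a | bad_b,
       report = data.frame(channel = rec$labels, mean_corr = mean_corr,
                           noise_var = noise_var, criterion = crit,
                           stringsAsFactors = FALSE))
}

#' Interpolate bad channels from their neighbors
#'
#' Each bad channel is replaced by the inverse-distance-weighted average of
#' its `k` nearest good channels.
#'
#' @param rec a `sensor_recording`.
#' @param bad_flags logical per channel; fewer than 25% may be bad.
#' @param k number of neighbor channels.
#' @return the repaired `sensor_recording` (with `bad_flags` recorded).
#' @export
interpolate_channels <- function(rec, bad_flags, k = 4) {
  if (!any(bad_flags)) { rec$bad_flags <- bad_flags; return(rec) }
  if (mean(bad_flags) >= 0.25) stop("too many bad channels")
  good <- which(!bad_flags)
  out <- rec
  for (b in which(bad_flags)) {
    d <- sqrt(colSums((t(rec$positions[good, , drop = FALSE]) -
                         rec$positions[b, ])^2))
    nb <- good[order(d)][seq_len(min(k, length(good)))]
    w <- 1 / pmax(sort(d)[seq_along(nb)], 1e-6)
    w <- w / sum(w)
    out$data[b, ] <- as.numeric(w %*% rec$data[nb, , drop = FALSE])
  }
  out$bad_flags <- bad_flags
  out
}

#' Zero-phase band-pass filter of a recording
#'
#' Forward-backward (zero-phase) 4th-order Butterworth band-pass applied
#' per channel.
#'
#' @param rec a `sensor_recording`.
#' @param lo,hi band edges in Hz; `hi` must be below Nyquist.
#' @return the filtered `sensor_recording`.
#' @export
bandpass_filter <- function(rec, lo = 1, hi = 80) {
  if (hi >= rec$fs / 2) stop("upper edge must be below Nyquist")
  bp <- signal::butter(4, c(lo, hi) / (rec$fs / 2), type = "pass")
  out <- rec
  out$data <- t(apply(rec$data, 1, function(x) signal::filtfilt(bp, x)))
  out
}

#' Classify artifactual independent components
#'
#' An IC is flagged as artifact if any of four scores crosses its
#' threshold: absolute correlation of the IC time-course with the EOG
#' reference or with the EMG reference; dissimilarity of the IC power
#' spectrum from a 1/f^beta line (Pearson correlation between the
#' log-spectrum over 2-40 Hz and its least-squares log-log fit — brain-like
#' spectra fit well, flat or peaked artifact spectra do not); and excess
#' kurtosis of the IC time-course (sparse transients).
#'
#' @param decomp an `ic_decomposition` of channel data.
#' @param eog_ref,emg_ref reference traces, same length as the IC
#'   time-courses.
#' @param fs sampling rate of the IC time-courses (Hz).
#' @param thresholds list: `eog`, `emg` (correlation cuts, default 0.3),
#'   `spec` (minimum 1/f fit correlation, default 0.5), `kurt` (maximum
#'   excess kurtosis, default 10).
#' @return list with `artifact_ids` and a `scores` data.frame.
#' @export
classify_artifact_ics <- function(decomp, eog_ref, emg_ref, fs,
                                  thresholds = list(eog = 0.3, emg = 0.3,
                                                    spec = 0.5, kurt = 10)) {
  k <- decomp$k
  sc <- data.frame(ic = seq_len(k), eog_corr = NA_real_, emg_corr = NA_real_,
                   spec_1f_sim = NA_real_, kurtosis = NA_real_)
  for (p in seq_len(k)) {
    s <- decomp$sources[p, ]
    sc$eog_corr[p] <- abs(safe_cor(s, eog_ref))
    sc$emg_corr[p] <- abs(safe_cor(s, emg_ref))
    sc$spec_1f_sim[p] <- one_over_f_similarity(s, fs)
    m <- mean(s); v <- mean((s - m)^2)
    sc$kurtosis[p] <- mean((s - m)^4) / v^2 - 3
  }
  flagged <- sc$eog_corr > thresholds$eog | sc$emg_corr > thresholds$emg |
    sc$spec_1f_sim < thresholds$spec | sc$kurtosis > thresholds$kurt
  list(artifact_ids = which(flagged), scores = sc)
}

# Pearson correlation between the 2-40 Hz log-spectrum and its fitted
# log-log (1/f^beta) line
one_over_f_similarity <- function(x, fs) {
  sp <- stft_power(x, fs)
  pw <- rowMeans(sp$power)
  sel <- sp$freqs >= 2 & sp$freqs <= 40
  lf <- log(sp$freqs[sel]); lp <- log(pmax(pw[sel], 1e-300))
  fit <- stats::lm.fit(cbind(1, lf), lp)
  safe_cor(fit$fitted.values, lp)
}

#' Remove artifact ICs and re-reference to the common average
#'
#' The channel data are reconstructed from the non-artifact independent
#' components (the DC offsets and any variance outside the retained IC
#' subspace are dropped, as in ICA denoising), then the channel mean at
#' each sample is subtracted (average reference).
#'
#' @param rec the `sensor_recording` the decomposition was fitted to.
#' @param decomp the `ic_decomposition`.
#' @param artifact_ids integer IDs of components to remove.
#' @return the cleaned, average-referenced `sensor_recording`.
#' @export
remove_ics_and_rereference <- function(rec, decomp, artifact_ids) {
  if (length(artifact_ids) &&
      (min(artifact_ids) < 1 || max(artifact_ids) > decomp$k))
    stop("invalid artifact component ids")
  keep <- setdiff(seq_len(decomp$k), artifact_ids)
  out <- rec
  recon <- if (length(keep))
    decomp$mixing[, keep, drop = FALSE] %*%
      decomp$sources[keep, , drop = FALSE]
  else matrix(0, nrow(rec$data), ncol(rec$data))
  out$data <- sweep(recon, 2, colMeans(recon))
  out
}
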