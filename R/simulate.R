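#' Simulate band-limited network sources on a voxel grid
#'
#' Each of `K` networks is a smooth nonnegative spatial blob whose voxels
#' carry a band-limited oscillation (the carrier, band-pass Gaussian noise
#' in the assigned band) amplitude-modulated by a slow envelope (rectified
#' low-pass Gaussian noise, cutoff `envelope_cutoff_hz`, default 0.1 Hz —
#' the timescale of resting-state hemodynamic fluctuations). Every voxel
#' additionally carries an independent 1/f background. The dipole
#' orientation of each voxel is fixed over time.
#'
#' @param grid a `source_grid`.
#' @param K number of networks (>= 1).
#' @param band_assignment character vector of length K of band names (see
#'   [eeg_bands()]), or a K x 2 matrix of custom band edges in Hz.
#' @param duration_s record length in seconds (>= 60).
#' @param fs sampling rate in Hz.
#' @param envelope_cutoff_hz low-pass cutoff of the slow envelopes.
#' @param seed integer seed.
#' @param network_amp amplitude of the modulated carrier at the blob center
#'   (arbitrary source units; the background has unit scale).
#' @param background_sd standard deviation of the per-voxel 1/f background.
#' @param map_seed seed for the network spatial layout; defaults to `seed`.
#'   Subjects of one cohort share `map_seed` (networks sit at the same
#'   anatomical location across subjects) while their time-courses, noise
#'   and artifacts differ through `seed`.
#' @return list with `activity` (class `source_activity`: `traces`
#'   n_voxels x samples, `orientations` n_voxels x 3 unit rows, `fs`) and
#'   `truth` (class `ground_truth`: `network_maps` n_voxels x K,
#'   `network_masks`, `envelopes` K x duration_s at 1 Hz, `carrier_bands`,
#'   `envelope_fs` = 1).
#' @export
simulate_sources <- function(grid, K, band_assignment, duration_s, fs,
                             envelope_cutoff_hz = 0.1, seed = 1,
                             network_amp = 1, background_sd = 1,
                             map_seed = seed) {
  stopifnot(K >= 1, duration_s >= 60, fs > 0)
  bands <- resolve_bands(band_assignment, K)
  if (any(bands[, 1] < 1) || any(bands[, 2] > 80))
    stop("carrier bands must lie within 1-80 Hz")
  if (envelope_cutoff_hz >= min(bands[, 1]))
    stop("envelope cutoff must be below the lowest carrier band edge")
  n <- round(duration_s * fs)
  nv <- grid$n_voxels

  # smooth spatial blobs with compact support, shared across a cohort
  blobs <- with_seed(map_seed, {
    centers <- sample(which(grid$gm_mask), K)
    maps <- matrix(0, nv, K)
    masks <- matrix(FALSE, nv, K)
    sig <- 1.6 * grid$spacing
    for (k in seq_len(K)) {
      d2 <- rowSums(sweep(grid$coords, 2, grid$coords[centers[k], ])^2)
      m <- exp(-d2 / (2 * sig^2))
      m[m < exp(-2)] <- 0          # truncate the Gaussian tail
      m[!grid$gm_mask] <- 0
      maps[, k] <- m
      masks[, k] <- m > 0
    }
    list(centers = centers, maps = maps, masks = masks)
  })
  centers <- blobs$centers; maps <- blobs$maps; masks <- blobs$masks

  with_seed(seed, {
    # slow envelopes generated at 1 Hz, rectified, interpolated to fs
    t1 <- seq_len(ceiling(duration_s))
    env1 <- matrix(0, K, length(t1))
    env_fs <- matrix(0, K, n)
    bl <- signal::butter(4, min(envelope_cutoff_hz / 0.5, 0.95), type = "low")
    tt <- (seq_len(n) - 1) / fs
    for (k in seq_len(K)) {
      e <- abs(signal::filtfilt(bl, stats::rnorm(length(t1) + 60)))
      e <- e[-(1:60)]
      env1[k, ] <- e
      env_fs[k, ] <- stats::approx(t1 - 0.5, e, xout = tt, rule = 2)$y
    }

    # band-limited carriers, unit variance; a long FIR keeps the carrier
    # power genuinely confined to the assigned band (steep skirts). Bands
    # are half-open [lo, hi), and the 1 Hz analysis bins integrate half a
    # bin either side of their center, so the passband stops 0.5 Hz short
    # of hi to keep carrier energy out of the next band's first bin.
    carriers <- matrix(0, K, n)
    for (k in seq_len(K)) {
      ord <- min(4L * fs, n %/% 3)
      bp <- signal::fir1(ord, c(bands[k, 1], bands[k, 2] - 0.5) / (fs / 2),
                         type = "pass")
      c0 <- signal::filtfilt(signal::Ma(bp), stats::rnorm(n + 2 * fs))
      c0 <- c0[(fs + 1):(fs + n)]
      carriers[k, ] <- c0 / stats::sd(c0)
    }

    traces <- matrix(0, nv, n)
    if (background_sd > 0) traces <- onef_noise(nv, n, fs) * background_sd
    for (k in seq_len(K)) {
      mod_k <- env_fs[k, ] * carriers[k, ]
      active <- which(maps[, k] > 0)
      if (length(active))
        traces[active, ] <- traces[active, ] +
          network_amp * maps[active, k, drop = FALSE] %*% rbind(mod_k)
    }

    orient <- matrix(stats::rnorm(3 * nv), nv, 3)
    orient <- orient / sqrt(rowSums(orient^2))

    list(
      activity = structure(list(traces = traces, orientations = orient,
                                fs = fs), class = "source_activity"),
      truth = structure(list(network_maps = maps, network_masks = masks,
                             envelopes = env1[, seq_len(ceiling(duration_s)),
                                              drop = FALSE],
                             carrier_bands = bands, envelope_fs = 1,
                             centers = centers),
                        class = "ground_truth")
    )
  })
}

resolve_bands <- function(band_assignment, K) {
  if (is.character(band_assignment)) {
    band_assignment <- rep_len(band_assignment, K)
    t(vapply(band_assignment, band_edges, numeric(2)))
  } else {
    b <- matrix(band_assignment, ncol = 2)
    b[rep_len(seq_len(nrow(b)), K), , drop = FALSE]
  }
}

# rows of 1/f-amplitude-shaped Gaussian noise, unit variance; the spectrum
# flattens below knee_hz, emulating the AC coupling of EEG amplifiers
onef_noise <- function(n_rows, n, fs, knee_hz = 0.5) {
  nf <- n %/% 2 + 1
  f <- (seq_len(nf) - 1) * fs / n
  shape <- c(0, 1 / sqrt(pmax(f[-1], knee_hz)))
  spec <- matrix(stats::rnorm(n_rows * nf) + 1i * stats::rnorm(n_rows * nf),
                 n_rows, nf)
  spec <- spec * rep(shape, each = n_rows)
  full <- matrix(0i, n_rows, n)
  full[, seq_len(nf)] <- spec
  if (n > 2) full[, n:(n - (nf - 3))] <- Conj(spec[, 2:(nf - 1)])
  x <- Re(t(stats::mvfft(t(full), inverse = TRUE))) / n
  x / sqrt(rowMeans(x^2) - rowMeans(x)^2)
}

#' Project source activity to EEG sensors
#'
#' Sensor data are the leadfield applied to the (fixed-orientation) dipole
#' moments plus white sensor noise: a purely linear forward model.
#'
#' @param leadfield a `leadfield` object.
#' @param source_activity a `source_activity` object.
#' @param sensor_noise_sd standard deviation of white sensor noise, in the
#'   units of the projected signal.
#' @param seed integer seed for the noise.
#' @return a `sensor_recording`: `data` channels x samples, `fs`, `labels`,
#'   `positions`, empty `tr_markers`/`cardiac_markers`, `bad_flags`.
#' @export
project_to_sensors <- function(leadfield, source_activity,
                               sensor_noise_sd = 0, seed = 1) {
  nv <- nrow(source_activity$traces)
  if (ncol(leadfield$matrix) != 3 * nv)
    stop("leadfield and source grid dimensions do not match")
  l_eff <- effective_leadfield(leadfield$matrix, source_activity$orientations)
  data <- l_eff %*% source_activity$traces
  if (sensor_noise_sd > 0)
    data <- data + with_seed(seed,
      matrix(stats::rnorm(length(data), sd = sensor_noise_sd), nrow(data)))
  n_s <- nrow(data)
  structure(list(data = data, fs = source_activity$fs,
                 labels = sprintf("E%03d", seq_len(n_s)),
                 positions = leadfield$sensor_positions,
                 tr_markers = integer(0), cardiac_markers = integer(0),
                 bad_flags = rep(FALSE, n_s)),
            class = "sensor_recording")
}

# collapse the 3 moment columns of each voxel onto its fixed orientation
effective_leadfield <- function(lf, orientations) {
  nv <- nrow(orientations)
  out <- matrix(0, nrow(lf), nv)
  for (a in 1:3)
    out <- out + lf[, seq(a, 3 * nv, by = 3), drop = FALSE] *
      rep(orientations[, a], each = nrow(lf))
  out
}

#' Contaminate an EEG recording with MR-environment artifacts
#'
#' Adds, in channel space: (i) a gradient artifact — a high-amplitude
#' waveform exactly periodic at the slice rate, starting at each TR onset;
#' (ii) a ballistocardiogram (BCG) artifact — a pulse-locked waveform at
#' cardiac R-peak markers with timing jitter and slow amplitude drift;
#' (iii) EOG blink transients weighted toward frontal sensors; and (iv)
#' band-limited EMG bursts weighted toward rim (low) sensors. TR and
#' cardiac markers are stored in the returned recording, and the pure
#' ocular/myogenic reference traces are attached for classifier use.
#'
#' Artifact amplitudes in `amp_cfg` are expressed as multiples of the clean
#' recording's overall RMS, so `gradient = 50` means a gradient waveform
#' 50 times the neural RMS.
#'
#' @param rec a clean `sensor_recording`.
#' @param tr_s fMRI repetition time in seconds.
#' @param slice_per_tr slices acquired per TR (gradient bursts per TR).
#' @param cardiac_bpm mean heart rate, 40-120 beats per minute.
#' @param jitter_ms standard deviation of R-peak timing jitter.
#' @param amp_cfg list with nonnegative `gradient`, `bcg`, `eog`, `emg`
#'   multipliers (0 disables a component).
#' @param seed integer seed.
#' @return the contaminated `sensor_recording`, with `tr_markers`,
#'   `cardiac_markers` and an `artifact_refs` element holding the EOG and
#'   EMG reference traces.
#' @export
add_mr_artifacts <- function(rec, tr_s = 2, slice_per_tr = 30,
                             cardiac_bpm = 70, jitter_ms = 20,
                             amp_cfg = list(gradient = 50, bcg = 5,
                                            eog = 3, emg = 2),
                             seed = 1) {
  stopifnot(tr_s > 0, cardiac_bpm >= 40, cardiac_bpm <= 120)
  amp <- amp_cfg
  for (nm in c("gradient", "bcg", "eog", "emg")) {
    if (is.null(amp[[nm]])) amp[[nm]] <- 0
    if (amp[[nm]] < 0) stop("artifact amplitude '", nm, "' must be >= 0")
  }
  fs <- rec$fs
  n <- ncol(rec$data)
  n_ch <- nrow(rec$data)
  rms0 <- sqrt(mean(rec$data^2))
  if (rms0 == 0) rms0 <- 1
  out <- rec

  with_seed(seed, {
    # --- gradient: exactly periodic at the slice rate, locked to TR onsets
    tr_len <- round(tr_s * fs)
    tr_markers <- seq(1L, n - tr_len + 1L, by = tr_len)
    if (amp$gradient > 0) {
      slice_len <- max(2L, round(tr_len / slice_per_tr))
      ts <- seq(0, 1, length.out = slice_len)
      wave <- sin(2 * pi * 3 * ts)^3 + 0.5 * sign(sin(2 * pi * 7 * ts))
      epoch <- rep_len(wave, tr_len)
      epoch <- epoch / sqrt(mean(epoch^2))
      gains <- stats::runif(n_ch, 0.7, 1.3)
      ga <- matrix(0, n_ch, n)
      for (m in tr_markers)
        ga[, m:(m + tr_len - 1L)] <- ga[, m:(m + tr_len - 1L)] +
          outer(gains, epoch)
      out$data <- out$data + amp$gradient * rms0 * ga
    }
    out$tr_markers <- as.integer(tr_markers)

    # --- BCG: jittered pulse train with slow amplitude drift
    ibi <- 60 / cardiac_bpm * fs
    n_beat_max <- ceiling(n / ibi) + 2L
    gaps <- ibi + stats::rnorm(n_beat_max, sd = jitter_ms / 1000 * fs)
    marks <- round(fs * 0.4 + cumsum(pmax(gaps, 0.3 * ibi)))
    marks <- marks[marks > 0.25 * fs & marks < n - 0.65 * fs]
    if (amp$bcg > 0 && length(marks)) {
      pl <- round(0.5 * fs)
      tp <- seq(0, 0.5, length.out = pl)
      pulse <- exp(-((tp - 0.25) / 0.13)^2) * sin(2 * pi * 3.5 * tp)
      pulse <- pulse / sqrt(mean(pulse^2))
      topo <- stats::runif(n_ch, 0.3, 1) * sample(c(-1, 1), n_ch, TRUE)
      drift <- 1 + 0.3 * sin(2 * pi * (seq_along(marks)) / 25)
      bcg <- matrix(0, n_ch, n)
      lag <- round(0.21 * fs)          # pulse artifact lags the R peak
      for (i in seq_along(marks)) {
        s <- marks[i] + lag
        if (s + pl - 1 > n) next
        bcg[, s:(s + pl - 1L)] <- bcg[, s:(s + pl - 1L)] +
          outer(topo * drift[i], pulse)
      }
      out$data <- out$data + amp$bcg * rms0 * bcg
    }
    out$cardiac_markers <- as.integer(marks)

    # --- EOG: blink transients, frontal weighting
    eog_ref <- numeric(n)
    if (amp$eog > 0) {
      blink_len <- round(0.3 * fs)
      bl_shape <- sin(pi * seq_len(blink_len) / blink_len)^2
      n_blinks <- max(1L, round(n / fs / 4))
      onsets <- sort(sample.int(n - blink_len, n_blinks))
      for (o in onsets)
        eog_ref[o:(o + blink_len - 1L)] <-
          eog_ref[o:(o + blink_len - 1L)] + bl_shape
      front <- pmax(rec$positions[, 2], 0)
      w_eog <- (front / max(front))^2
      out$data <- out$data + amp$eog * rms0 * outer(w_eog, eog_ref)
    }

    # --- EMG: 20-70 Hz bursts, rim weighting (the beta/gamma range where
    # muscle activity contaminates EEG)
    emg_ref <- numeric(n)
    if (amp$emg > 0) {
      hi <- min(70, 0.4 * fs)
      bp <- signal::butter(4, c(20, hi) / (fs / 2), type = "pass")
      base <- signal::filtfilt(bp, stats::rnorm(n))
      gate <- numeric(n)
      n_bursts <- max(1L, round(n / fs / 10))
      bl <- round(2 * fs)
      for (o in sort(sample.int(n - bl, n_bursts)))
        gate[o:(o + bl - 1L)] <- 1
      emg_ref <- base * gate
      emg_ref <- emg_ref / max(stats::sd(emg_ref), 1e-12)
      zr <- rec$positions[, 3]
      w_emg <- ((max(zr) - zr) / (max(zr) - min(zr)))^2
      out$data <- out$data + amp$emg * rms0 * outer(w_emg, emg_ref)
    }

    out$artifact_refs <- list(eog = eog_ref, emg = emg_ref)
    out
  })
}

#' Simulate a BOLD volume series from network ground truth
#'
#' Voxel v's BOLD series is the sum over networks of the voxel's map
#' loading times the canonical-HRF-convolved network envelope, evaluated at
#' volume times `t_j = j * tr_s`, plus an optional second-order Legendre
#' polynomial drift per voxel and white noise.
#'
#' @param ground_truth a `ground_truth` from [simulate_sources()].
#' @param grid the matching `source_grid`.
#' @param tr_s repetition time in seconds.
#' @param n_volumes number of volumes; `n_volumes * tr_s` must not exceed
#'   the envelope duration.
#' @param noise_sd white noise standard deviation.
#' @param drift_cfg list with `amp` (0 disables drift).
#' @param seed integer seed.
#' @return a `volume_series`: `values` n_voxels x n_volumes, `tr`,
#'   `grid_ref`.
#' @export
simulate_bold <- function(ground_truth, grid, tr_s = 2, n_volumes,
                          noise_sd = 0, drift_cfg = list(amp = 0), seed = 1) {
  env <- ground_truth$envelopes
  dur <- ncol(env)
  if (n_volumes * tr_s > dur + 1e-9)
    stop("requested BOLD duration exceeds the envelope duration")
  K <- nrow(env)
  hrf <- canonical_hrf(dt = 1)
  t_env <- seq_len(dur) - 0.5                  # envelope frame centers
  t_vol <- (seq_len(n_volumes) - 1) * tr_s
  conv_env <- matrix(0, K, n_volumes)
  for (k in seq_len(K)) {
    ce <- hrf_convolve(env[k, ], hrf)
    conv_env[k, ] <- stats::approx(t_env, ce, xout = t_vol, rule = 2)$y
  }
  values <- ground_truth$network_maps %*% conv_env
  with_seed(seed, {
    if (!is.null(drift_cfg$amp) && drift_cfg$amp > 0) {
      u <- seq(-1, 1, length.out = n_volumes)
      leg <- cbind(u, 0.5 * (3 * u^2 - 1))
      coefs <- matrix(stats::rnorm(2 * grid$n_voxels, sd = drift_cfg$amp),
                      grid$n_voxels, 2)
      values <- values + coefs %*% t(leg)
    }
    if (noise_sd > 0)
      values <- values + matrix(stats::rnorm(length(values), sd = noise_sd),
                                nrow(values))
  })
  structure(list(values = values, tr = tr_s, grid_ref = grid$shape),
            class = "volume_series")
}

#' Simulate one complete synthetic subject
#'
#' Convenience wrapper chaining the head model, source simulation, sensor
#' projection, MR artifact contamination and BOLD generation with one
#' configuration (see [default_config()]). All randomness derives from
#' `config$seed` plus `subject`.
#'
#' @param config configuration list; missing entries take defaults.
#' @param subject subject index (offsets the seed).
#' @param head optional precomputed head model to share across subjects.
#' @return list with `grid`, `leadfield`, `clean_rec`, `rec` (contaminated),
#'   `bold`, `truth`, `subject`.
#' @export
simulate_subject <- function(config = default_config(), subject = 1,
                             head = NULL) {
  cf <- merge_config(config)
  seed <- cf$seed + 1000L * subject
  if (is.null(head))
    head <- make_head_model(cf$n_sensors, cf$grid_shape, cf$spacing_mm,
                            seed = cf$seed)
  src <- simulate_sources(head$grid, cf$K, cf$band_assignment, cf$duration_s,
                          cf$fs, cf$envelope_cutoff_hz, seed = seed,
                          network_amp = cf$network_amp,
                          background_sd = cf$background_sd,
                          map_seed = cf$seed)
  clean <- project_to_sensors(head$leadfield, src$activity,
                              sensor_noise_sd = 0)
  noise_sd <- cf$sensor_noise_rel * sqrt(mean(clean$data^2))
  clean_n <- project_to_sensors(head$leadfield, src$activity,
                                sensor_noise_sd = noise_sd, seed = seed + 1)
  rec <- add_mr_artifacts(clean_n, cf$tr_s, cf$slice_per_tr, cf$cardiac_bpm,
                          cf$jitter_ms, cf$amp_cfg, seed = seed + 2)
  n_vol <- floor(cf$duration_s / cf$tr_s)
  bold_sd <- cf$bold_noise_rel *
    stats::sd(ground_truth_bold_scale(src$truth))
  bold <- simulate_bold(src$truth, head$grid, cf$tr_s, n_vol,
                        noise_sd = bold_sd, drift_cfg = cf$drift_cfg,
                        seed = seed + 3)
  list(grid = head$grid, leadfield = head$leadfield, clean_rec = clean,
       pre_artifact_rec = clean_n, rec = rec, bold = bold,
       truth = src$truth, subject = subject)
}

# typical in-network noiseless BOLD scale, used to set relative noise
ground_truth_bold_scale <- function(truth) {
  hrf <- canonical_hrf(dt = 1)
  ce <- hrf_convolve(truth$envelopes[1, ], hrf)
  ce * max(truth$network_maps[, 1])
}

#' Default synthetic-study configuration
#'
#' Desk-scale defaults: 32 sensors, a 6 x 6 x 6 grid at 6 mm spacing
#' (216 voxels), 300 s at fs = 250 Hz, TR = 2 s, one alpha-carrier network,
#' unit-scale 1/f background, mild sensor and BOLD noise, and MR artifact
#' amplitudes dominated by the gradient (50 x neural RMS).
#'
#' @return a named list of parameters.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    n_subjects = 10L,
    n_sensors = 32L,
    grid_shape = c(6L, 6L, 6L),
    spacing_mm = 6,
    K = 1L,
    band_assignment = "alpha",
    duration_s = 300,
    fs = 250,
    envelope_cutoff_hz = 0.1,
    network_amp = 2,
    background_sd = 1,
    sensor_noise_rel = 0.05,
    tr_s = 2,
    slice_per_tr = 30L,
    cardiac_bpm = 70,
    jitter_ms = 20,
    amp_cfg = list(gradient = 50, bcg = 5, eog = 3, emg = 2),
    bold_noise_rel = 0.3,
    drift_cfg = list(amp = 0.1),
    occipital_channels = NULL,   # filled from sensor geometry when NULL
    bands = eeg_bands()$band,
    alpha_reg = 0.05,
    n_avg_epochs = 20L,
    n_obs_pcs = 3L,
    ic_thresholds = list(eog = 0.3, emg = 0.3, spec = 0.5, kurt = 10),
    k_max = 5,
    fdr_q = 0.05,
    binarize_rule = "fdr"
  )
}

merge_config <- function(config) {
  cf <- default_config()
  for (nm in names(config)) cf[[nm]] <- config[[nm]]
  cf
}
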