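# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small head model: 16 sensors, 4x4x4 grid
test_head <- function() {
  cached("head", make_head_model(16, c(4, 4, 4), spacing_mm = 6, seed = 42))
}

# reduced study configuration used by pipeline-level tests
test_config <- function() {
  cf <- default_config()
  cf$n_sensors <- 16L
  cf$grid_shape <- c(4L, 4L, 4L)
  cf$duration_s <- 80
  cf$fs <- 200
  cf$n_subjects <- 3L
  cf$seed <- 7L
  cf
}

test_subject <- function() {
  cached("subject", {
    cf <- test_config()
    simulate_subject(cf, 1, head = test_head())
  })
}

# per-artifact contaminated copies of the standard fixture, sharing the
# same underlying clean recording
artifact_fixture <- function(which = c("gradient", "bcg")) {
  which <- match.arg(which)
  cached(paste0("artifact_", which), {
    cf <- test_config()
    amp <- list(gradient = 0, bcg = 0, eog = 0, emg = 0)
    amp[[which]] <- default_config()$amp_cfg[[which]]
    cf$amp_cfg <- amp
    simulate_subject(cf, 1, head = test_head())
  })
}

# mean band power of a multichannel matrix via the package STFT engine
mean_band_power <- function(data, fs, lo, hi) {
  mean(vapply(seq_len(nrow(data)), function(i) {
    sp <- stft_power(data[i, ], fs)
    mean(bandbold:::band_mean_power(sp, lo, hi))
  }, numeric(1)))
}

# RMS of the cardiac-epoch-locked average residual relative to a reference
bcg_locked_rms <- function(rec, ref_data, markers = rec$cardiac_markers) {
  fs <- rec$fs
  lo <- round(-0.2 * fs); hi <- round(0.6 * fs) - 1
  m <- markers[markers + lo >= 1 & markers + hi <= ncol(rec$data)]
  v <- vapply(seq_len(nrow(rec$data)), function(ch) {
    x <- rec$data[ch, ] - ref_data[ch, ]
    e <- bandbold:::epoch_matrix(x, m, lo, hi)
    mean(colMeans(e)^2)
  }, numeric(1))
  sqrt(mean(v))
}

# synthetic ECG: sharp R waves at the requested rate
synth_ecg <- function(bpm, duration_s, fs, seed = 1) {
  n <- round(duration_s * fs)
  x <- numeric(n)
  period <- 60 / bpm * fs
  marks <- round(seq(fs * 0.3, n - fs * 0.2, by = period))
  spike <- exp(-((seq(-0.05, 0.05, by = 1 / fs)) / 0.012)^2)
  for (m in marks) {
    idx <- m + seq_along(spike) - 1
    idx <- idx[idx <= n]
    x[idx] <- x[idx] + spike[seq_along(idx)]
  }
  set.seed(seed)
  x + rnorm(n, sd = 0.02)
}
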