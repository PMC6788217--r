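test_that("AAS removes an exactly periodic gradient artifact", {
  sub <- artifact_fixture("gradient")
  pre <- sub$pre_artifact_rec
  g <- remove_gradient_artifact(sub$rec,
                                n_avg_epochs = length(sub$rec$tr_markers),
                                n_obs_pcs = 0)
  art_before <- mean((sub$rec$data - pre$data)^2)
  art_after <- mean((g$rec$data - pre$data)^2)
  expect_gt(10 * log10(art_before / art_after), 40)
  # clean alpha content preserved within 1 dB
  a_pre <- mean_band_power(pre$data, pre$fs, 8, 13)
  a_post <- mean_band_power(g$rec$data, pre$fs, 8, 13)
  expect_lt(abs(10 * log10(a_post / a_pre)), 1)
})

test_that("gradient removal identities and OBS improvement hold", {
  sub <- artifact_fixture("gradient")
  # zero input stays zero through AAS + OBS
  zero <- sub$rec
  zero$data <- zero$data * 0
  gz <- remove_gradient_artifact(zero, 5, 0)
  expect_equal(max(abs(gz$rec$data)), 0)
  expect_error(remove_gradient_artifact(
    structure(list(data = zero$data, fs = 200, tr_markers = integer(0)),
              class = "sensor_recording")), "markers")

  # drifting-amplitude artifact: adding OBS PCs improves on AAS alone
  pre <- sub$pre_artifact_rec
  drift <- sub$rec
  m <- drift$tr_markers
  len <- min(diff(m))
  gain <- 1 + 0.5 * sin(2 * pi * seq_along(m) / 20)
  art <- sub$rec$data - pre$data
  for (i in seq_along(m)) {
    idx <- m[i]:(m[i] + len - 1)
    drift$data[, idx] <- pre$data[, idx] + gain[i] * art[, idx]
  }
  aas <- remove_gradient_artifact(drift, n_avg_epochs = 10, n_obs_pcs = 0)
  obs <- remove_gradient_artifact(drift, n_avg_epochs = 10, n_obs_pcs = 3)
  r_aas <- mean((aas$rec$data - pre$data)^2)
  r_obs <- mean((obs$rec$data - pre$data)^2)
  expect_lte(r_obs, r_aas)
})

test_that("OBS reduces the BCG while sparing alpha", {
  sub <- artifact_fixture("bcg")
  pre <- sub$pre_artifact_rec
  b <- remove_bcg_artifact(sub$rec, n_obs_pcs = 3)
  red <- 20 * log10(bcg_locked_rms(sub$rec, pre$data) /
                      bcg_locked_rms(b$rec, pre$data))
  expect_gt(red, 10)
  a_pre <- mean_band_power(pre$data, pre$fs, 8, 13)
  a_post <- mean_band_power(b$rec$data, pre$fs, 8, 13)
  expect_lt(abs(10 * log10(a_post / a_pre)), 3)

  # zero components: exact identity
  b0 <- remove_bcg_artifact(sub$rec, n_obs_pcs = 0)
  expect_identical(b0$rec$data, sub$rec$data)

  # shuffled markers cannot do as well as the true ones
  sh <- sub$rec
  set.seed(31)
  sh$cardiac_markers <- sort(sample(seq(200, ncol(sh$data) - 200),
                                    length(sh$cardiac_markers)))
  bs <- remove_bcg_artifact(sh, n_obs_pcs = 3)
  red_sh <- 20 * log10(
    bcg_locked_rms(sub$rec, pre$data) /
      bcg_locked_rms(bs$rec, pre$data, markers = sub$rec$cardiac_markers))
  expect_lt(red_sh, red)
})

test_that("R-peak detection counts and spaces beats correctly", {
  ecg <- synth_ecg(60, 60, 250)
  peaks <- detect_r_peaks(ecg, 250)
  expect_gte(length(peaks), 59)
  expect_lte(length(peaks), 61)

  expect_identical(detect_r_peaks(numeric(3000), 250), integer(0))

  ecg90 <- synth_ecg(90, 60, 250)
  p90 <- detect_r_peaks(ecg90, 250)
  expect_equal(median(diff(p90)) / 250, 0.667, tolerance = 0.03)
  expect_error(detect_r_peaks(numeric(100), 250), "10 s")
})

test_that("bad-channel detection flags a broadband-noise channel only", {
  sub <- test_subject()
  rec <- sub$pre_artifact_rec
  set.seed(41)
  rec$data[5, ] <- 100 * sd(rec$data) * rnorm(ncol(rec$data))
  out <- suppressWarnings(detect_bad_channels(rec))
  expect_true(out$bad_flags[5])
  expect_equal(sum(out$bad_flags), 1)

  # identical clean channels: no outlier exists
  same <- rec
  same$data <- matrix(rep(rec$data[1, ], nrow(rec$data)),
                      nrow = nrow(rec$data), byrow = TRUE)
  expect_false(any(suppressWarnings(detect_bad_channels(same))$bad_flags))

  # flags invariant to channel ordering
  perm <- sample(nrow(rec$data))
  rp <- rec
  rp$data <- rec$data[perm, ]
  rp$positions <- rec$positions[perm, ]
  rp$labels <- rec$labels[perm]
  out_p <- suppressWarnings(detect_bad_channels(rp))
  expect_identical(out_p$bad_flags, out$bad_flags[perm])
})

test_that("interpolation replaces bad channels with neighbor averages", {
  sub <- test_subject()
  rec <- sub$pre_artifact_rec
  # a channel relocated to the centroid of 4 identical neighbors
  nb <- 1:4
  rec$data[nb[2], ] <- rec$data[nb[1], ]
  rec$data[nb[3], ] <- rec$data[nb[1], ]
  rec$data[nb[4], ] <- rec$data[nb[1], ]
  rec$positions[5, ] <- colMeans(rec$positions[nb, ])
  # move every other channel far away so nb are the 4 nearest
  far <- setdiff(seq_len(nrow(rec$data)), c(nb, 5))
  rec$positions[far, ] <- rec$positions[far, ] + 500
  flags <- rep(FALSE, nrow(rec$data)); flags[5] <- TRUE
  out <- interpolate_channels(rec, flags)
  expect_equal(out$data[5, ], rec$data[nb[1], ], tolerance = 1e-9)

  # no flags: identity
  out2 <- interpolate_channels(rec, rep(FALSE, nrow(rec$data)))
  expect_identical(out2$data, rec$data)

  # interpolated variance bounded by the largest neighbor variance
  flags2 <- rep(FALSE, nrow(rec$data)); flags2[7] <- TRUE
  out3 <- interpolate_channels(sub$pre_artifact_rec, flags2)
  d <- sqrt(colSums((t(sub$pre_artifact_rec$positions[-7, ]) -
                       sub$pre_artifact_rec$positions[7, ])^2))
  nb_var <- apply(sub$pre_artifact_rec$data[-7, ][order(d)[1:4], ], 1, var)
  expect_lte(var(out3$data[7, ]), max(nb_var))

  too_many <- rep(TRUE, nrow(rec$data))
  expect_error(interpolate_channels(rec, too_many), "too many")
})

test_that("band-pass filter has the stated pass and stop behavior", {
  fs <- 250
  t <- seq(0, 20, by = 1 / fs)
  mk <- function(x) structure(list(data = rbind(x), fs = fs),
                              class = "sensor_recording")
  mid <- seq(5 * fs, 15 * fs)   # avoid edge transients
  s10 <- sin(2 * pi * 10 * t)
  f10 <- bandpass_filter(mk(s10), 1, 80)$data[1, ]
  expect_equal(max(abs(f10[mid])), 1, tolerance = 0.01)

  s01 <- sin(2 * pi * 0.1 * t)
  f01 <- bandpass_filter(mk(s01), 1, 80)$data[1, ]
  expect_lt(20 * log10(max(abs(f01[mid]))), -20)

  dc <- rep(5, length(t))
  fdc <- bandpass_filter(mk(dc), 1, 80)$data[1, ]
  expect_lt(mean(abs(fdc[mid])), 1e-3 * 5)
  expect_error(bandpass_filter(mk(s10), 1, 130), "Nyquist")
})

test_that("IC classification scores and flags behave as designed", {
  fs <- 200
  n <- 60 * fs
  set.seed(51)
  eog <- numeric(n)
  onsets <- seq(400, n - 400, by = 4 * fs)
  for (o in onsets) eog[o:(o + 59)] <- sin(pi * (1:60) / 60)^2
  emg <- rnorm(n)
  # build a decomposition whose sources we control
  brain <- bandbold:::onef_noise(2, n, fs)
  spikes <- numeric(n); spikes[sample(n, 30)] <- 8
  src <- rbind(eog / sd(eog), brain, spikes / sd(spikes))
  dec <- structure(list(k = 4, sources = src, mixing = diag(4),
                        whitening = diag(4), row_means = rep(0, 4),
                        convergence = rep(1L, 4), seed = 1),
                   class = "ic_decomposition")
  out <- classify_artifact_ics(dec, eog, emg, fs)
  expect_equal(out$scores$eog_corr[1], 1, tolerance = 1e-9)
  expect_true(1 %in% out$artifact_ids)        # EOG copy
  expect_false(2 %in% out$artifact_ids)       # 1/f brain source
  expect_false(3 %in% out$artifact_ids)
  expect_gt(out$scores$kurtosis[4], 10)       # sparse spike train
  expect_true(4 %in% out$artifact_ids)
  expect_gt(out$scores$spec_1f_sim[2], 0.5)
})

test_that("IC removal and average reference identities hold", {
  set.seed(52)
  n <- 4000
  x <- matrix(rnorm(5 * n), 5) + matrix(rexp(5 * n), 5)
  x <- x - rowMeans(x)
  rec <- structure(list(data = x, fs = 100), class = "sensor_recording")
  dec <- fastica_deflation(x, 5, seed = 1)

  out <- remove_ics_and_rereference(rec, dec, integer(0))
  ref <- sweep(x, 2, colMeans(x))
  expect_equal(out$data, ref, tolerance = 1e-9)

  out_all <- remove_ics_and_rereference(rec, dec, 1:5)
  expect_equal(max(abs(out_all$data)), 0)

  out1 <- remove_ics_and_rereference(rec, dec, 2)
  expect_lt(max(abs(colMeans(out1$data))), 1e-12)
  expect_error(remove_ics_and_rereference(rec, dec, 9), "invalid")
})

test_that("the cleaning cascade reduces artifacts monotonically and keeps alpha", {
  sub <- test_subject()
  cf <- test_config()
  pre <- sub$pre_artifact_rec
  g <- remove_gradient_artifact(sub$rec, cf$n_avg_epochs, cf$n_obs_pcs)
  b <- remove_bcg_artifact(g$rec, cf$n_obs_pcs)
  p_raw <- mean((sub$rec$data - pre$data)^2)
  p_g <- mean((g$rec$data - pre$data)^2)
  p_b <- mean((b$rec$data - pre$data)^2)
  expect_true(p_raw > p_g && p_g > p_b)

  pp <- preprocess_recording(sub$rec, cf)
  pre_ref <- sweep(pre$data, 2, colMeans(pre$data))
  a_clean <- mean_band_power(pre_ref, pre$fs, 8, 13)
  a_out <- mean_band_power(pp$rec$data, pre$fs, 8, 13)
  expect_lt(abs(10 * log10(a_out / a_clean)), 3)

  # no operator altered rate, channel count or markers
  expect_identical(pp$rec$fs, sub$rec$fs)
  expect_identical(nrow(pp$rec$data), nrow(sub$rec$data))
  expect_identical(pp$rec$tr_markers, sub$rec$tr_markers)
  expect_identical(pp$rec$cardiac_markers, sub$rec$cardiac_markers)
})
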