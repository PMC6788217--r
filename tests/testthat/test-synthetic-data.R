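test_that("an alpha carrier network concentrates its power in 8-13 Hz", {
  hm <- test_head()
  src <- simulate_sources(hm$grid, 1, "alpha", 60, 200, seed = 3,
                          background_sd = 0)
  v <- which(src$truth$network_masks[, 1])[1]
  sp <- stats::spec.pgram(src$activity$traces[v, ], plot = FALSE, taper = 0)
  f <- sp$freq * 200
  frac <- sum(sp$spec[f >= 8 & f <= 13]) / sum(sp$spec)
  expect_gt(frac, 0.95)
})

test_that("zero envelope leaves background only; generation is deterministic", {
  hm <- test_head()
  src <- simulate_sources(hm$grid, 1, "alpha", 60, 100, seed = 5,
                          network_amp = 0)
  bg <- simulate_sources(hm$grid, 1, "alpha", 60, 100, seed = 5,
                         network_amp = 1)
  # with the network amplitude at zero the traces are the pure background
  v_out <- which(!src$truth$network_masks[, 1])[1]
  expect_equal(src$activity$traces[v_out, ], bg$activity$traces[v_out, ])
  src2 <- simulate_sources(hm$grid, 1, "alpha", 60, 100, seed = 5,
                           network_amp = 0)
  expect_identical(src$activity$traces, src2$activity$traces)
  expect_identical(src$truth$envelopes, src2$truth$envelopes)
})

test_that("ground truth structure is valid and band errors are caught", {
  hm <- test_head()
  src <- simulate_sources(hm$grid, 2, c("alpha", "theta"), 60, 100, seed = 1)
  expect_true(all(src$truth$envelopes >= 0))
  expect_true(all(colSums(src$truth$network_maps > 0) >= 1))
  expect_equal(rowSums(src$activity$orientations^2),
               rep(1, hm$grid$n_voxels))
  expect_error(simulate_sources(hm$grid, 1, matrix(c(0.5, 10), 1), 60, 100),
               "1-80")
  expect_error(simulate_sources(hm$grid, 1, "alpha", 30, 100))
})

test_that("sensor projection is linear in the sources", {
  hm <- test_head()
  src <- simulate_sources(hm$grid, 1, "alpha", 60, 100, seed = 2)
  zero <- src$activity
  zero$traces <- zero$traces * 0
  rec0 <- project_to_sensors(hm$leadfield, zero)
  expect_true(all(rec0$data == 0))

  rec1 <- project_to_sensors(hm$leadfield, src$activity)
  dbl <- src$activity
  v <- which(src$truth$network_masks[, 1])[1]
  dbl$traces[v, ] <- 2 * dbl$traces[v, ]
  rec2 <- project_to_sensors(hm$leadfield, dbl)
  # doubling one voxel's moment doubles exactly its sensor contribution
  single <- src$activity
  single$traces[-v, ] <- 0
  recv <- project_to_sensors(hm$leadfield, single)
  expect_equal(rec2$data, rec1$data + recv$data, tolerance = 1e-9)
})

test_that("MR artifacts behave per construction", {
  sub <- test_subject()
  clean <- sub$pre_artifact_rec
  # gradient at 50x neural RMS inflates variance by >= 1000x
  ratio <- mean(apply(sub$rec$data, 1, stats::var)) /
    mean(apply(clean$data, 1, stats::var))
  expect_gt(ratio, 1000)
  # all amplitudes zero: identity (markers still attached)
  same <- add_mr_artifacts(clean, amp_cfg = list(gradient = 0, bcg = 0,
                                                 eog = 0, emg = 0), seed = 1)
  expect_equal(same$data, clean$data)
  expect_gt(length(same$tr_markers), 0)
  # cardiac marker spacing tracks the heart rate
  gaps <- diff(sub$rec$cardiac_markers) / sub$rec$fs
  expect_equal(median(gaps), 60 / 70, tolerance = 0.05)
  expect_error(add_mr_artifacts(clean, amp_cfg = list(gradient = -1)),
               "must be >= 0")
})

test_that("BOLD generation follows the HRF-convolved envelope coupling", {
  hm <- test_head()
  src <- simulate_sources(hm$grid, 1, "alpha", 120, 100, seed = 4)
  # zero envelopes, zero noise, zero drift -> all-zero series
  gt0 <- src$truth
  gt0$envelopes <- gt0$envelopes * 0
  b0 <- simulate_bold(gt0, hm$grid, 2, 60)
  expect_true(all(b0$values == 0))

  # short boxcar envelope at onset 20 s: peak lag within [24, 27] s
  gt1 <- src$truth
  gt1$envelopes[1, ] <- 0
  gt1$envelopes[1, 21] <- 1
  b1 <- simulate_bold(gt1, hm$grid, tr_s = 0.5, n_volumes = 200)
  v <- which.max(gt1$network_maps[, 1])
  t_peak <- (which.max(b1$values[v, ]) - 1) * 0.5
  expect_gte(t_peak, 24); expect_lte(t_peak, 27)
  # independent oracle: canonical double-gamma convolved with the boxcar
  # on a fine grid peaks at onset + mode + half-width ~ 25-26 s
  tg <- seq(0, 60, by = 0.01)
  hrf_fine <- stats::dgamma(tg, 6, 1) - stats::dgamma(tg, 16, 1) / 6
  box <- as.numeric(tg >= 20 & tg < 21)
  conv_fine <- stats::convolve(box, rev(hrf_fine), type = "open")[seq_along(tg)]
  expect_equal(t_peak, tg[which.max(conv_fine)], tolerance = 1.5)

  # out-of-network voxel, noiseless -> identically zero (drift disabled)
  v_out <- which(rowSums(gt1$network_maps) == 0)[1]
  expect_true(all(b1$values[v_out, ] == 0))

  # coupling consistency: noiseless in-network BOLD correlates 1 with the
  # HRF-convolved envelope
  b2 <- simulate_bold(src$truth, hm$grid, 2, 60)
  ce <- hrf_convolve(src$truth$envelopes[1, ], canonical_hrf(1))
  ce_tr <- stats::approx(seq_len(120) - 0.5, ce, xout = (0:59) * 2,
                         rule = 2)$y
  v <- which.max(src$truth$network_maps[, 1])
  expect_equal(stats::cor(b2$values[v, ], ce_tr), 1, tolerance = 1e-9)

  expect_error(simulate_bold(src$truth, hm$grid, 2, 100), "duration")
})

test_that("the gradient artifact is exactly epoch-periodic given markers", {
  sub <- artifact_fixture("gradient")
  ga <- sub$rec$data - sub$pre_artifact_rec$data
  m <- sub$rec$tr_markers
  len <- min(diff(m))
  e <- bandbold:::epoch_matrix(ga[1, ], m, 0, len - 1)
  # floating-point recovery of the additive artifact leaves rounding at
  # the level of the (much smaller) underlying signal
  dev <- max(abs(sweep(e, 2, e[1, ])))
  expect_lt(dev, 1e-9 * max(abs(ga)))
})
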