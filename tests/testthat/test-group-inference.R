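test_that("the one-sample one-sided t-test matches its distributional oracle", {
  z0 <- matrix(0, 5, 8)
  out <- group_ttest(z0, "pos")
  expect_equal(out$t, rep(0, 8))
  expect_equal(out$p, rep(0.5, 8))

  set.seed(91)
  z <- matrix(rnorm(20, mean = 0.5, sd = 0.1), 20, 1)
  out2 <- group_ttest(z, "pos")
  expect_lt(out2$p[1], 1e-6)
  # oracle: t.test in the same direction
  tt <- t.test(z[, 1], alternative = "greater")
  expect_equal(out2$t[1], unname(tt$statistic))
  expect_equal(out2$p[1], tt$p.value)

  # negation swaps the one-sided directions
  zz <- matrix(rnorm(40), 8, 5)
  expect_equal(group_ttest(-zz, "pos")$p, group_ttest(zz, "neg")$p)
  expect_error(group_ttest(zz[1:2, ]), "3 subjects")

  # degenerate sd = 0 limit
  zc <- matrix(rep(c(2, -1, 0), each = 4), 4)
  dp <- group_ttest(zc, "pos")
  expect_equal(dp$p, c(0, 1, 0.5))
})

test_that("BY-FDR matches the brute-force threshold table", {
  # worked example: m = 4, c(4) = 25/12; thresholds i*q/(m*c(m))
  p <- c(0.001, 0.01, 0.03, 0.8)
  cm <- sum(1 / (1:4))
  expect_equal(cm, 25 / 12)
  thr <- (1:4) * 0.05 / (4 * cm)
  expect_equal(thr, c(0.006, 0.012, 0.018, 0.024))
  k <- max(which(sort(p) <= thr))        # brute-force step-up
  expect_equal(k, 2L)
  mask <- by_fdr(p, q = 0.05)
  expect_equal(sum(mask), 2L)
  expect_true(all(mask[1:2]))

  expect_equal(sum(by_fdr(rep(1, 10))), 0L)
  expect_true(by_fdr(0.01, q = 0.05))    # m = 1 reduces to plain threshold
  expect_error(by_fdr(c(0.5, 1.2)), "0, 1")

  # random p-sets: package mask equals the brute-force step-up rule
  set.seed(92)
  for (i in 1:20) {
    p <- runif(50)^2
    ps <- sort(p)
    thr <- (1:50) * 0.05 / (50 * sum(1 / (1:50)))
    k <- if (any(ps <= thr)) max(which(ps <= thr)) else 0L
    expect_equal(sum(by_fdr(p, 0.05)), k)
    if (k > 0) expect_true(all(by_fdr(p, 0.05)[order(p)[1:k]]))
  }
})

test_that("BY controls the FDR under the planted-signal simulation", {
  set.seed(93)
  fdrs <- numeric(200)
  bh_ge_by <- TRUE
  for (r in 1:200) {
    p_null <- runif(1000)
    p_sig <- rbeta(100, 0.05, 1)
    p <- c(p_null, p_sig)
    rej <- by_fdr(p, 0.05)
    fdrs[r] <- if (any(rej)) sum(rej[1:1000]) / sum(rej) else 0
    if (sum(rej) > sum(p.adjust(p, "BH") <= 0.05)) bh_ge_by <- FALSE
  }
  se <- sqrt(var(fdrs) / 200)
  expect_lte(mean(fdrs), 0.05 + 2 * max(se, 1e-3))
  expect_true(bh_ge_by)   # BY never rejects more than BH
})

test_that("overlap metrics reproduce the Dice and Pearson identities", {
  a <- c(rep(TRUE, 6), rep(FALSE, 6))
  expect_equal(overlap_metrics(rnorm(12), rnorm(12),
                               binary_a = a, binary_b = a)$dc, 1)
  b <- c(rep(FALSE, 6), rep(TRUE, 6))
  expect_equal(overlap_metrics(rnorm(12), rnorm(12),
                               binary_a = a, binary_b = b)$dc, 0)

  # |A| = 4, |B| = 6, |A n B| = 3 -> DC = 0.6
  aa <- c(rep(TRUE, 4), rep(FALSE, 8))
  bb <- c(rep(TRUE, 3), FALSE, rep(TRUE, 3), rep(FALSE, 5))
  expect_equal(overlap_metrics(rnorm(12), rnorm(12),
                               binary_a = aa, binary_b = bb)$dc, 0.6)

  # perfectly linear maps -> CC = 1
  m1 <- c(1, 2, 3, 4); m2 <- c(2, 4, 6, 8)
  res <- overlap_metrics(m1, m2, binary_a = m1 > 0, binary_b = m2 > 0)
  expect_equal(res$cc, 1)

  expect_error(overlap_metrics(m1, m2, mask = rep(FALSE, 4)), "empty")
  expect_warning(
    res0 <- overlap_metrics(m1, m2, binary_a = rep(FALSE, 4),
                            binary_b = rep(FALSE, 4)),
    "empty")
  expect_equal(res0$dc, 0)
})

test_that("group maps honor the correction scope and mask invariants", {
  set.seed(94)
  z <- matrix(rnorm(10 * 50, mean = rep(c(1.2, 0), c(10, 40))), 10, 50,
              byrow = FALSE)
  z[, 1:10] <- z[, 1:10] + 1
  gm <- group_map(z, q = 0.05)
  expect_true(all(gm$p_pos[gm$mask_pos] <= 0.05))
  # a joint correction family can only shrink the mask
  gm_joint <- group_map(z, q = 0.05, extra_p_pos = runif(500, 0.5, 1),
                        extra_p_neg = runif(500, 0.5, 1))
  expect_true(all(gm_joint$mask_pos <= gm$mask_pos))
  expect_identical(gm_joint$scope, "voxels_x_bands")
})
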