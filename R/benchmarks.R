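#' Point-source localization benchmark for the eLORETA inverse
#'
#' Builds the synthetic head model, computes the inverse operator, and
#' feeds it noise-free sensor potentials from randomly chosen single
#' dipoles; a trial is a hit when the voxel with maximal estimated source
#' power is the true source voxel.
#'
#' @param n_sources number of random point-source trials.
#' @param n_sensors sensors in the head model.
#' @param grid_shape voxel grid shape.
#' @param alpha_reg eLORETA regularization fraction.
#' @param seed integer seed.
#' @return list with `hits` and `n`.
#' @export
benchmark_eloreta_localization <- function(n_sources = 50, n_sensors = 32,
                                           grid_shape = c(6, 6, 6),
                                           alpha_reg = 0.05, seed = 1) {
  hm <- make_head_model(n_sensors, grid_shape, seed = seed)
  op <- compute_eloreta_operator(hm$leadfield, alpha_reg)
  with_seed(seed + 1, {
    vs <- sample(hm$grid$n_voxels, n_sources, replace = TRUE)
    hits <- 0L
    for (v in vs) {
      m <- stats::rnorm(3)
      phi <- hm$leadfield$matrix[, (3 * v - 2):(3 * v)] %*% m
      pw <- source_power_per_voxel(apply_inverse(op, phi))
      if (which.max(pw) == v) hits <- hits + 1L
    }
    list(hits = hits, n = n_sources)
  })
}

#' Blind-source-separation benchmark on known Laplacian mixtures
#'
#' Mixes two independent Laplacian sources with a random well-conditioned
#' 2 x 2 matrix and scores FastICA recovery by the Amari index against the
#' true mixing, over several seeds.
#'
#' @param n_runs number of independent mixtures.
#' @param n_obs samples per mixture.
#' @param seed integer seed.
#' @return numeric vector of Amari indices.
#' @export
benchmark_ica_amari <- function(n_runs = 10, n_obs = 5000, seed = 1) {
  with_seed(seed, {
    vapply(seq_len(n_runs), function(r) {
      s <- matrix(sample(c(-1, 1), 2 * n_obs, TRUE) * stats::rexp(2 * n_obs),
                  2)
      repeat {
        a <- matrix(stats::rnorm(4), 2)
        if (abs(det(a)) > 0.3) break
      }
      dec <- fastica_deflation(a %*% s, 2, seed = seed + r)
      amari_index(dec$mixing, a)
    }, numeric(1))
  })
}

#' Model-order benchmark for the MDL criterion
#'
#' White Gaussian noise (true order 0) and four planted independent
#' non-Gaussian components in weak noise (true order 4), both at
#' dim = 20, n = 20000.
#'
#' @param seed integer seed.
#' @return list with `order_white` and `order_planted`.
#' @export
benchmark_mdl <- function(seed = 1) {
  with_seed(seed, {
    wn <- matrix(stats::rnorm(20 * 20000), 20)
    s <- matrix(sample(c(-1, 1), 4 * 20000, TRUE) * stats::rexp(4 * 20000),
                4)
    a <- matrix(stats::rnorm(80), 20, 4)
    x <- a %*% s + 0.05 * matrix(stats::rnorm(20 * 20000), 20)
    list(order_white = estimate_order_mdl(wn),
         order_planted = estimate_order_mdl(x))
  })
}

#' Artifact-cleaning benchmark on fixtures with known clean truth
#'
#' Three measurements on synthetic subjects sharing one configuration:
#' (i) gradient artifact reduction by AAS with the template averaged over
#' all epochs (exact-periodic case), as residual power before/after in dB;
#' (ii) BCG reduction as the epoch-locked mean RMS before/after OBS, in
#' dB; (iii) alpha-band power distortion through the full cascade
#' (gradient + BCG + bad channels + filter + ICA + average reference)
#' against the average-referenced clean truth, in dB.
#'
#' @param config study configuration (generator defaults).
#' @return list with `gradient_db`, `bcg_db`, `cascade_alpha_db`.
#' @export
benchmark_cleaning <- function(config = default_config()) {
  cf <- merge_config(config)
  band_pow <- function(data, fs) {
    mean(vapply(seq_len(nrow(data)), function(i)
      mean(band_mean_power(stft_power(data[i, ], fs), 8, 13)), numeric(1)))
  }

  cfg <- cf
  cfg$amp_cfg <- list(gradient = cf$amp_cfg$gradient, bcg = 0, eog = 0,
                      emg = 0)
  sg <- simulate_subject(cfg, 1)
  g <- remove_gradient_artifact(sg$rec,
                                n_avg_epochs = length(sg$rec$tr_markers),
                                n_obs_pcs = 0)
  pre <- sg$pre_artifact_rec$data
  gradient_db <- db_ratio(mean((sg$rec$data - pre)^2),
                          mean((g$rec$data - pre)^2))

  cfb <- cf
  cfb$amp_cfg <- list(gradient = 0, bcg = cf$amp_cfg$bcg, eog = 0, emg = 0)
  sb <- simulate_subject(cfb, 1)
  b <- remove_bcg_artifact(sb$rec, n_obs_pcs = cf$n_obs_pcs)
  lock_rms <- function(rec, ref) {
    fs <- rec$fs
    lo <- round(-0.2 * fs); hi <- round(0.6 * fs) - 1
    m <- rec$cardiac_markers
    m <- m[m + lo >= 1 & m + hi <= ncol(rec$data)]
    v <- vapply(seq_len(nrow(rec$data)), function(ch) {
      e <- epoch_matrix(rec$data[ch, ] - ref[ch, ], m, lo, hi)
      mean(colMeans(e)^2)
    }, numeric(1))
    sqrt(mean(v))
  }
  pre_b <- sb$pre_artifact_rec$data
  bcg_db <- 20 * log10(lock_rms(sb$rec, pre_b) / lock_rms(b$rec, pre_b))

  sub <- simulate_subject(cf, 1)
  pp <- preprocess_recording(sub$rec, cf)
  pre_ref <- sweep(sub$pre_artifact_rec$data, 2,
                   colMeans(sub$pre_artifact_rec$data))
  cascade_alpha_db <- db_ratio(band_pow(pp$rec$data, cf$fs),
                               band_pow(pre_ref, cf$fs))
  list(gradient_db = gradient_db, bcg_db = bcg_db,
       cascade_alpha_db = cascade_alpha_db)
}

#' Empirical FDR benchmark for the BY procedure
#'
#' The worked step-up example (m = 4) plus a planted-signal simulation:
#' per replicate, 1000 null p-values ~ Uniform(0,1) and 100 signal
#' p-values ~ Beta(0.05, 1); the false discovery proportion of [by_fdr()]
#' is averaged over replicates.
#'
#' @param n_reps replicates.
#' @param m_null,m_sig null and signal counts per replicate.
#' @param q FDR level.
#' @param seed integer seed.
#' @return list with `worked_rejections`, `fdr_mean`, `fdr_se`,
#'   `bh_never_fewer` (BY rejected no more than BH in every replicate).
#' @export
benchmark_by_fdr <- function(n_reps = 200, m_null = 1000, m_sig = 100,
                             q = 0.05, seed = 1) {
  worked <- sum(by_fdr(c(0.001, 0.01, 0.03, 0.8), q = 0.05))
  with_seed(seed, {
    fdp <- numeric(n_reps)
    dominated <- TRUE
    for (r in seq_len(n_reps)) {
      p <- c(stats::runif(m_null), stats::rbeta(m_sig, 0.05, 1))
      rej <- by_fdr(p, q)
      fdp[r] <- if (any(rej)) sum(rej[seq_len(m_null)]) / sum(rej) else 0
      if (sum(rej) > sum(stats::p.adjust(p, "BH") <= q)) dominated <- FALSE
    }
    list(worked_rejections = worked, fdr_mean = mean(fdp),
         fdr_se = sqrt(stats::var(fdp) / n_reps),
         bh_never_fewer = dominated)
  })
}

#' Reduced-scale study configuration
#'
#' The configuration used for repeated end-to-end studies: generator
#' defaults with a shorter record (120 s), fs = 200 Hz and a 5 x 5 x 5
#' grid, so that a full 10-subject group analysis runs in about a minute.
#'
#' @return a configuration list.
#' @export
small_study_config <- function() {
  cf <- default_config()
  cf$duration_s <- 120
  cf$fs <- 200
  cf$grid_shape <- c(5L, 5L, 5L)
  cf
}

#' Spectral-specificity benchmark of the full pipeline
#'
#' Repeats the complete group analysis (10 synthetic subjects with an
#' alpha-carrier ground-truth network) for several master seeds and counts
#' the seeds in which the alpha column of the CC/DC report strictly
#' exceeds the delta, theta, beta and gamma columns in both rows.
#'
#' @param n_seeds number of master seeds.
#' @param base_seed first master seed.
#' @param config study configuration (default [small_study_config()]).
#' @return list with `wins` (both rows strict), `wins_cc` (CC row strict),
#'   `n_seeds`, and the per-seed `tables`.
#' @export
benchmark_spectral_specificity <- function(n_seeds = 10, base_seed = 1,
                                           config = small_study_config()) {
  other <- c("Delta", "Theta", "Beta", "Gamma")
  tables <- vector("list", n_seeds)
  wins <- 0L; wins_cc <- 0L
  for (i in seq_len(n_seeds)) {
    cf <- merge_config(config)
    cf$seed <- base_seed + i - 1L
    g <- run_group(cf)
    tables[[i]] <- g$table
    cc_ok <- g$table["CC", "Alpha"] > max(g$table["CC", other])
    dc_ok <- g$table["DC", "Alpha"] > max(g$table["DC", other])
    wins_cc <- wins_cc + cc_ok
    wins <- wins + (cc_ok && dc_ok)
  }
  list(wins = wins, wins_cc = wins_cc, n_seeds = n_seeds, tables = tables)
}
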