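#' Full EEG cleaning cascade for one recording
#'
#' Gradient AAS+OBS removal, BCG OBS removal, bad-channel detection and
#' interpolation, 1-80 Hz zero-phase band-pass, ICA-based rejection of
#' ocular/myogenic components, and average re-referencing, in that order.
#'
#' @param rec a contaminated `sensor_recording` (markers present; EOG/EMG
#'   reference traces in `rec$artifact_refs` are used by the IC
#'   classifier when available).
#' @param config configuration list (see [default_config()]).
#' @return list with the cleaned `rec`, per-step `reports`, `bad_flags`,
#'   and the IC classifier `scores`.
#' @export
preprocess_recording <- function(rec, config = default_config()) {
  cf <- merge_config(config)
  reports <- list()
  g <- remove_gradient_artifact(rec, cf$n_avg_epochs, cf$n_obs_pcs)
  reports$gradient <- g$report
  b <- remove_bcg_artifact(g$rec, cf$n_obs_pcs)
  reports$bcg <- b$report
  bad <- suppressWarnings(detect_bad_channels(b$rec))
  reports$bad_channels <- bad$report
  r2 <- interpolate_channels(b$rec, bad$bad_flags)
  r3 <- bandpass_filter(r2, 1, min(80, 0.45 * r2$fs))
  k <- max(2L, estimate_order_mdl(r3$data))
  dec <- fastica_deflation(r3$data, k, seed = cf$seed)
  eog <- rec$artifact_refs$eog %||% numeric(ncol(rec$data))
  emg <- rec$artifact_refs$emg %||% numeric(ncol(rec$data))
  cls <- classify_artifact_ics(dec, eog, emg, r3$fs, cf$ic_thresholds)
  clean <- remove_ics_and_rereference(r3, dec, cls$artifact_ids)
  clean$tr_markers <- rec$tr_markers
  clean$cardiac_markers <- rec$cardiac_markers
  list(rec = clean, reports = reports, bad_flags = bad$bad_flags,
       scores = cls$scores, removed_ics = cls$artifact_ids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the subject-level analysis chain
#'
#' Preprocess the EEG, reconstruct sources with eLORETA, compute band
#' power, detect networks per band by temporal ICA with template
#' selection, build HRF-convolved regressors (per-band network IC
#' time-course plus the occipital sensor alpha power), and correlate each
#' voxelwise with the upsampled BOLD. Also runs spatial ICA on the
#' subject's BOLD to extract the fMRI-side network map.
#'
#' @param config configuration list.
#' @param subject subject index.
#' @param data optional subject data (as from [simulate_subject()]).
#' @param inv_op optional precomputed `inverse_operator` (shared head).
#' @param head optional precomputed head model.
#' @return list with `zmaps_network` (per band), `zmap_sensor`,
#'   `networks`, `fmri_network`, `preprocess`, `subject`.
#' @export
run_subject <- function(config = default_config(), subject = 1,
                        data = NULL, inv_op = NULL, head = NULL) {
  cf <- merge_config(config)
  if (is.null(data)) data <- simulate_subject(cf, subject, head = head)
  pp <- preprocess_recording(data$rec, cf)
  if (is.null(inv_op))
    inv_op <- compute_eloreta_operator(data$leadfield, cf$alpha_reg)
  est <- apply_inverse(inv_op, pp$rec)
  bands <- cf$bands
  power <- compute_band_power(est, bands = bands)
  template <- data$truth$network_maps[, 1]
  gm <- data$grid$gm_mask
  hrf <- canonical_hrf(dt = 1)
  bold_1hz <- upsample_bold(data$bold, to_rate = 1)

  networks <- list()
  zmaps_network <- list()
  for (b in bands) {
    nr <- suppressWarnings(
      detect_networks_tica(power[[b]], k_max = cf$k_max, template = template,
                           mask = gm, seed = cf$seed + subject))
    reg <- hrf_convolve(nr$timecourse, hrf)
    zm <- correlate_voxelwise(align_power_regressor(reg, power[[b]]$times),
                              bold_1hz)
    zm$band <- b
    zm$regressor_kind <- "network_ic"
    networks[[b]] <- nr
    zmaps_network[[b]] <- zm
  }

  occ <- cf$occipital_channels %||% default_occipital(pp$rec)
  sens_reg <- occipital_power_regressor(pp$rec, occ, band = "alpha")
  zs <- correlate_voxelwise(
    align_power_regressor(hrf_convolve(sens_reg, hrf),
                          seq_along(sens_reg) + 1), bold_1hz)
  zs$band <- "alpha"
  zs$regressor_kind <- "occipital_sensor"

  fmri <- suppressWarnings(
    detect_networks_sica(data$bold, k_max = cf$k_max, template = template,
                         mask = gm, seed = cf$seed + subject))
  list(zmaps_network = zmaps_network, zmap_sensor = zs,
       networks = networks, fmri_network = fmri, preprocess = pp,
       subject = subject, grid = data$grid, truth = data$truth)
}

# pad a 1 Hz regressor whose first frame is centered at times[1] so that
# its samples line up with the BOLD grid starting at t = 0
align_power_regressor <- function(reg, times) {
  off <- round(times[1])
  c(rep(reg[1], off), as.numeric(reg))
}

# default occipital selection for the synthetic montage: the sensors
# furthest toward the back (most negative y)
default_occipital <- function(rec, n = 5) {
  rec$labels[order(rec$positions[, 2])[seq_len(n)]]
}

#' Run the group-level analysis
#'
#' Simulates (or accepts) a cohort of subjects, runs the subject chain on
#' each, stacks the subject Fisher-z maps, and performs group inference:
#' one-sample one-sided t-tests per voxel with BY-FDR correction — per
#' band over voxels for the sensor-level variant, jointly over voxels and
#' bands for the network-level variant — plus the fMRI-sICA group network
#' map. Finally the spatial overlap (CC and Dice) of each band's EEG
#' network group map with the fMRI group map is tabulated.
#'
#' @param config configuration list.
#' @param subjects optional list of precomputed [run_subject()] results.
#' @return list with `table` (rows CC/DC, one column per band),
#'   `group_network` (per-band `group_map`), `group_fmri`, `group_sensor`,
#'   `overlap` (per band), `subjects`.
#' @export
run_group <- function(config = default_config(), subjects = NULL) {
  cf <- merge_config(config)
  if (is.null(subjects)) {
    head <- make_head_model(cf$n_sensors, cf$grid_shape, cf$spacing_mm,
                            seed = cf$seed)
    inv_op <- compute_eloreta_operator(head$leadfield, cf$alpha_reg)
    subjects <- lapply(seq_len(cf$n_subjects), function(s)
      run_subject(cf, s, inv_op = inv_op, head = head))
  }
  if (length(subjects) < 3) stop("need at least 3 completed subjects")
  bands <- cf$bands
  gm <- subjects[[1]]$grid$gm_mask

  # the mass-univariate family is the gray matter (the voxels analyzed),
  # expanded back to the full grid for map output
  z_net <- lapply(bands, function(b)
    do.call(rbind, lapply(subjects, function(s) s$zmaps_network[[b]]$z)))
  names(z_net) <- bands
  # joint correction family: all bands' gray-matter p-values together
  p_fam <- lapply(bands, function(b) {
    pos <- group_ttest(z_net[[b]][, gm, drop = FALSE], "pos")$p
    neg <- group_ttest(z_net[[b]][, gm, drop = FALSE], "neg")$p
    list(pos = pos, neg = neg)
  })
  names(p_fam) <- bands
  group_network <- lapply(bands, function(b) {
    others <- setdiff(bands, b)
    gmap <- group_map(z_net[[b]][, gm, drop = FALSE], q = cf$fdr_q,
                      extra_p_pos = unlist(lapply(p_fam[others], `[[`, "pos")),
                      extra_p_neg = unlist(lapply(p_fam[others], `[[`, "neg")))
    expand_group_map(gmap, gm)
  })
  names(group_network) <- bands

  z_fmri <- do.call(rbind, lapply(subjects, function(s)
    s$fmri_network$spatial_zmap))
  group_fmri <- expand_group_map(group_map(z_fmri[, gm, drop = FALSE],
                                           q = cf$fdr_q), gm)

  z_sens <- do.call(rbind, lapply(subjects, function(s) s$zmap_sensor$z))
  group_sensor <- expand_group_map(group_map(z_sens[, gm, drop = FALSE],
                                             q = cf$fdr_q), gm)

  overlap <- lapply(bands, function(b) {
    ga <- group_network[[b]]
    if (identical(cf$binarize_rule, "fdr")) {
      suppressWarnings(
        overlap_metrics(ga$t, group_fmri$t, mask = gm,
                        binary_a = ga$mask_pos & gm,
                        binary_b = group_fmri$mask_pos & gm))
    } else {
      suppressWarnings(overlap_metrics(ga$t, group_fmri$t, mask = gm))
    }
  })
  names(overlap) <- bands

  tab <- rbind(CC = vapply(overlap, function(o) o$cc, numeric(1)),
               DC = vapply(overlap, function(o) o$dc, numeric(1)))
  colnames(tab) <- tools::toTitleCase(bands)
  list(table = tab, group_network = group_network,
       group_fmri = group_fmri, group_sensor = group_sensor,
       overlap = overlap, subjects = subjects, config = cf)
}

# scatter a gray-matter group map back onto the full grid (t = 0, p = 1,
# masks FALSE outside gray matter)
expand_group_map <- function(gmap, gm) {
  nv <- length(gm)
  full <- function(x, fill) { out <- rep(fill, nv); out[gm] <- x; out }
  gmap$t <- full(gmap$t, 0)
  gmap$p_pos <- full(gmap$p_pos, 1)
  gmap$p_neg <- full(gmap$p_neg, 1)
  gmap$mask_pos <- full(gmap$mask_pos, FALSE)
  gmap$mask_neg <- full(gmap$mask_neg, FALSE)
  gmap
}

#' Write group results to disk
#'
#' Volumes (group t maps and significance masks, per band and for the
#' fMRI network) are written as NIfTI-1 on the grid's affine; the CC/DC
#' table as tab-delimited text; the configuration as YAML; and a run log
#' with package/R versions, the master seed and the configuration hash.
#'
#' @param results a [run_group()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_group_results <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grid <- results$subjects[[1]]$grid
  for (b in names(results$group_network)) {
    gmap <- results$group_network[[b]]
    write_volume_nifti(gmap$t, grid, file.path(dir, paste0("t_", b, ".nii")))
    write_volume_nifti(as.numeric(gmap$mask_pos), grid,
                       file.path(dir, paste0("mask_pos_", b, ".nii")))
  }
  write_volume_nifti(results$group_fmri$t, grid,
                     file.path(dir, "t_fmri_network.nii"))
  utils::write.table(results$table, file.path(dir, "overlap_table.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(config_for_yaml(results$config), cfg_path)
  writeLines(c(
    paste0("bandbold ", as.character(utils::packageVersion("bandbold")),
           " / R ", getRversion()),
    paste0("master_seed: ", results$config$seed),
    paste0("n_subjects: ", length(results$subjects)),
    paste0("config_md5: ", unname(tools::md5sum(cfg_path)))),
    file.path(dir, "run_log.txt"))
  invisible(dir)
}

config_for_yaml <- function(cf) {
  cf$bands <- as.list(cf$bands)
  cf
}

#' Write a voxel map as a 3-D NIfTI volume
#'
#' @param values numeric vector, one value per grid voxel.
#' @param grid the `source_grid` (its shape and spacing set the affine).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(values, grid, path) {
  arr <- array(values, dim = grid$shape)
  img <- RNifti::asNifti(arr, pixdim = rep(grid$spacing, 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a voxel map from a 3-D NIfTI volume
#'
#' @param path NIfTI file path.
#' @return numeric vector of voxel values in grid order.
#' @export
read_volume_nifti <- function(path) {
  as.numeric(RNifti::readNifti(path))
}

#' Load a study configuration from YAML
#'
#' Reads the file, validates entry names and basic types against
#' [default_config()], and merges with defaults.
#'
#' @param path YAML file path.
#' @return validated configuration list.
#' @export
read_config <- function(path) {
  cf <- yaml::read_yaml(path)
  known <- names(default_config())
  unknown <- setdiff(names(cf), known)
  if (length(unknown))
    stop("unknown configuration entries: ", paste(unknown, collapse = ", "))
  num_fields <- c("duration_s", "fs", "tr_s", "cardiac_bpm", "alpha_reg",
                  "fdr_q", "network_amp", "background_sd")
  for (nm in intersect(num_fields, names(cf)))
    if (!is.numeric(cf[[nm]]) || cf[[nm]] <= 0)
      stop("configuration entry '", nm, "' must be a positive number")
  if (!is.null(cf$bands)) cf$bands <- unlist(cf$bands)
  merge_config(cf)
}
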