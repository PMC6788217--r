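#' Detect networks from band power by temporal ICA
#'
#' Runs FastICA on the voxels x time band-power matrix to obtain temporally
#' independent component time-courses (model order from
#' [estimate_order_mdl()] unless given). The spatial map of each IC is the
#' per-voxel Pearson correlation of the IC time-course with that voxel's
#' power series, Fisher r-to-z transformed; a voxel with constant power
#' gets z = 0 with a warning. When a template map is supplied the IC with
#' the highest within-mask spatial correlation is selected.
#'
#' @param power a `band_power_series`.
#' @param k model order; `NULL` selects it by MDL (at least 1).
#' @param k_max upper bound on the model order. MDL assumes many more
#'   observations than variables; on short desk-scale records the noise
#'   eigenvalue spread inflates its estimate, so the order is capped
#'   (and always bounded by the data rank).
#' @param template optional template map (length n_voxels) for selection.
#' @param mask optional logical voxel mask for template matching.
#' @param seed ICA seed.
#' @return object of class `network_result`: `band`, `decomposition`,
#'   `zmaps` (n_voxels x k), `timecourses` (k x T, 1 Hz), `template_r`,
#'   `selected_ic`, `selected_r`, `spatial_zmap`, `timecourse`.
#' @export
detect_networks_tica <- function(power, k = NULL, k_max = 12,
                                 template = NULL, mask = NULL, seed = 1) {
  x <- power$values
  if (is.null(k)) k <- max(1L, min(estimate_order_mdl(x), k_max))
  k <- min(k, data_rank(x))
  dec <- fastica_deflation(x, k, seed = seed)
  zmaps <- matrix(0, nrow(x), k)
  n_const <- 0L
  sds <- apply(x, 1, stats::sd)
  for (p in seq_len(k)) {
    r <- row_cor(x, dec$sources[p, ])
    zmaps[, p] <- fisher_z(r)
  }
  if (any(sds == 0)) {
    n_const <- sum(sds == 0)
    warning(n_const, " voxel(s) with constant power: z set to 0",
            call. = FALSE)
  }
  res <- structure(list(band = power$band, decomposition = dec,
                        zmaps = zmaps,
                        timecourses = dec$sources,
                        template_r = NULL, selected_ic = NA_integer_,
                        selected_r = NA_real_, spatial_zmap = NULL,
                        timecourse = NULL, kind = "tica"),
                   class = "network_result")
  if (!is.null(template)) res <- select_by_template(res, template, mask)
  res
}

#' Detect networks from BOLD by spatial ICA
#'
#' Runs FastICA with volumes as the mixed signals and voxels as
#' observations, so the recovered sources are spatially independent maps
#' and the mixing columns are their time-courses. Each map is z-scored by
#' subtracting its mean across voxels and dividing by the standard
#' deviation across voxels.
#'
#' @param bold a `volume_series` with >= 30 volumes.
#' @param k model order; `NULL` selects it by MDL (at least 1).
#' @param k_max upper bound on the model order (see
#'   [detect_networks_tica()]).
#' @param template,mask optional template map and mask for selection.
#' @param seed ICA seed.
#' @return a `network_result` with `zmaps` (z-scored maps), `timecourses`
#'   (k x n_volumes at TR rate).
#' @export
detect_networks_sica <- function(bold, k = NULL, k_max = 12,
                                 template = NULL, mask = NULL, seed = 1) {
  if (ncol(bold$values) < 30) stop("need at least 30 volumes")
  x <- t(bold$values)                      # volumes x voxels
  if (all(apply(x, 1, stats::sd) < 1e-14)) stop("degenerate data")
  if (is.null(k)) k <- max(1L, min(estimate_order_mdl(x), k_max))
  k <- min(k, data_rank(x))
  dec <- fastica_deflation(x, k, seed = seed)
  # component sign fixed on the spatial map (positive skewness: compact
  # activations come out positive), mirroring the time-course
  for (p in seq_len(k)) {
    s <- dec$sources[p, ]
    if (mean((s - mean(s))^3) < 0) {
      dec$sources[p, ] <- -s
      dec$mixing[, p] <- -dec$mixing[, p]
    }
  }
  maps <- t(dec$sources)                   # voxels x k
  maps <- scale(maps)                      # mean 0, sd 1 across voxels
  attr(maps, "scaled:center") <- NULL
  attr(maps, "scaled:scale") <- NULL
  res <- structure(list(band = "bold", decomposition = dec,
                        zmaps = maps,
                        timecourses = t(dec$mixing),
                        template_r = NULL, selected_ic = NA_integer_,
                        selected_r = NA_real_, spatial_zmap = NULL,
                        timecourse = NULL, kind = "sica"),
                   class = "network_result")
  if (!is.null(template)) res <- select_by_template(res, template, mask)
  res
}

select_by_template <- function(res, template, mask = NULL) {
  m <- match_template(res$zmaps, template, mask)
  res$template_r <- m$r
  res$selected_ic <- m$selected
  res$selected_r <- m$r[m$selected]
  res$spatial_zmap <- res$zmaps[, m$selected]
  res$timecourse <- res$timecourses[m$selected, ]
  res
}

#' Select the candidate map best matching a template
#'
#' Pearson correlation, within the mask, between each candidate map column
#' and the template; the candidate with the highest correlation is
#' selected, ties broken by the lower index.
#'
#' @param maps n_voxels x k candidate maps.
#' @param template_map length-n_voxels template.
#' @param mask optional logical voxel mask (default all voxels).
#' @return list with `selected` (index) and `r` (per-candidate correlation).
#' @export
match_template <- function(maps, template_map, mask = NULL) {
  maps <- as.matrix(maps)
  if (is.null(mask)) mask <- rep(TRUE, nrow(maps))
  if (!any(mask)) stop("empty mask")
  tm <- template_map[mask]
  r <- unname(apply(maps[mask, , drop = FALSE], 2,
                    function(m) safe_cor(m, tm)))
  list(selected = unname(which.max(r)), r = r)
}
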