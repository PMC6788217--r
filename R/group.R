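#' One-sample one-sided t-test per voxel
#'
#' Mass-univariate one-sample t-test of stacked subject z-maps against 0
#' with n - 1 degrees of freedom, returning the one-sided p-value for the
#' requested direction. A voxel with zero variance across subjects takes
#' the degenerate limit: p = 0 when its mean lies strictly in the tested
#' direction, p = 1 otherwise.
#'
#' @param zmaps n_subjects x n_voxels matrix.
#' @param side `"pos"` (mean > 0) or `"neg"` (mean < 0).
#' @return list with `t` and `p` per voxel, plus `df` and `n_subjects`.
#' @export
group_ttest <- function(zmaps, side = c("pos", "neg")) {
  side <- match.arg(side)
  zmaps <- as.matrix(zmaps)
  n <- nrow(zmaps)
  if (n < 3) stop("need at least 3 subjects")
  m <- colMeans(zmaps)
  s <- apply(zmaps, 2, stats::sd)
  t_stat <- ifelse(s > 0, m / (s / sqrt(n)), ifelse(m > 0, Inf,
                                                    ifelse(m < 0, -Inf, 0)))
  p <- if (side == "pos") stats::pt(t_stat, df = n - 1, lower.tail = FALSE)
  else stats::pt(t_stat, df = n - 1, lower.tail = TRUE)
  deg <- s == 0
  if (any(deg)) {
    dir_ok <- if (side == "pos") m[deg] > 0 else m[deg] < 0
    p[deg] <- ifelse(dir_ok, 0, ifelse(m[deg] == 0, 0.5, 1))
  }
  list(t = ifelse(is.finite(t_stat), t_stat,
                  sign(t_stat) * .Machine$double.xmax^0.25),
       p = p, df = n - 1, n_subjects = n)
}

#' Benjamini-Yekutieli FDR rejection mask
#'
#' Step-up procedure valid under arbitrary dependence: sort the m p-values
#' ascending and reject the k smallest, where k is the largest i with
#' `p(i) <= i * q / (m * c(m))` and `c(m) = sum_{j=1}^m 1/j`.
#'
#' @param pvals p-values in `[0, 1]`.
#' @param q target false discovery rate.
#' @return logical rejection mask, same length as `pvals`.
#' @export
by_fdr <- function(pvals, q = 0.05) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BY") <= q
}

#' Group-level map with BY-FDR-significant masks
#'
#' Runs the one-sided group t-test in both directions and derives
#' BY-FDR-corrected significance masks. The correction scope can include
#' several bands jointly: pass `extra_p` with the p-values of the other
#' maps sharing the correction family, and only this map's mask is
#' returned while thresholds are computed over the whole family.
#'
#' @param zmaps n_subjects x n_voxels matrix.
#' @param q FDR level.
#' @param extra_p_pos,extra_p_neg optional p-values from other maps in the
#'   same correction family.
#' @return object of class `group_map`: `t`, `p_pos`, `p_neg`, `q`,
#'   `mask_pos`, `mask_neg`, `n_subjects`, `scope`.
#' @export
group_map <- function(zmaps, q = 0.05, extra_p_pos = NULL,
                      extra_p_neg = NULL) {
  pos <- group_ttest(zmaps, "pos")
  neg <- group_ttest(zmaps, "neg")
  nv <- length(pos$p)
  mask_pos <- by_fdr(c(pos$p, extra_p_pos), q)[seq_len(nv)]
  mask_neg <- by_fdr(c(neg$p, extra_p_neg), q)[seq_len(nv)]
  structure(list(t = pos$t, p_pos = pos$p, p_neg = neg$p, q = q,
                 mask_pos = mask_pos, mask_neg = mask_neg,
                 n_subjects = pos$n_subjects,
                 scope = if (is.null(extra_p_pos)) "voxels"
                 else "voxels_x_bands"),
            class = "group_map")
}

#' Spatial overlap of two network maps
#'
#' CC: Pearson correlation between the unthresholded map values within the
#' mask. DC: Dice coefficient `2 |A n B| / (|A| + |B|)` of the binarized
#' maps; the binarization is supplied by `binary_a`/`binary_b` (e.g.
#' BY-FDR-significant positive masks) or by a z > `z_cut` rule on the map
#' values.
#'
#' @param map_a,map_b numeric maps on the same grid.
#' @param mask logical voxel mask for the CC (must be non-empty).
#' @param binary_a,binary_b optional logical masks for the Dice
#'   coefficient; when `NULL`, `map > z_cut` within `mask` is used.
#' @param z_cut threshold for the fallback binarization rule.
#' @return object of class `overlap_result`: `cc`, `dc`.
#' @export
overlap_metrics <- function(map_a, map_b, mask = NULL,
                            binary_a = NULL, binary_b = NULL,
                            z_cut = 1.96) {
  if (is.null(mask)) mask <- rep(TRUE, length(map_a))
  if (!any(mask)) stop("empty mask")
  cc <- safe_cor(map_a[mask], map_b[mask])
  if (is.null(binary_a)) binary_a <- (map_a > z_cut) & mask
  if (is.null(binary_b)) binary_b <- (map_b > z_cut) & mask
  na <- sum(binary_a); nb <- sum(binary_b)
  if (na + nb == 0) {
    warning("both binary sets empty: Dice defined as 0", call. = FALSE)
    dc <- 0
  } else {
    dc <- 2 * sum(binary_a & binary_b) / (na + nb)
  }
  structure(list(cc = cc, dc = dc), class = "overlap_result")
}
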