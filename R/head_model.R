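#' Build a synthetic head model: source grid and leadfield
#'
#' Constructs a regular voxel grid of current-dipole source locations and a
#' set of EEG sensors on an upper-hemisphere shell around the grid, then
#' computes the leadfield with the closed-form potential of a current dipole
#' in an infinite homogeneous conductor and applies an average reference.
#' The closed form is a deliberately simple stand-in for a realistic
#' volume-conductor model: it is exact for its own geometry, fast, and
#' sufficient to exercise a linear inverse.
#'
#' @param n_sensors number of sensors (>= 8).
#' @param grid_shape integer vector of 3 voxel counts per axis (>= 27 voxels
#'   in total).
#' @param spacing_mm grid spacing in mm (default 6).
#' @param seed integer seed controlling the small deterministic jitter of
#'   sensor positions.
#' @param conductivity_s_m conductivity of the homogeneous medium (S/m).
#' @return list with elements `grid` (class `source_grid`: `coords`
#'   n_voxels x 3 mm, `spacing`, `gm_mask`, `n_voxels`) and `leadfield`
#'   (class `leadfield`: `matrix` sensors x (3 n_voxels), `sensor_positions`,
#'   `reference = "average"`).
#' @export
make_head_model <- function(n_sensors, grid_shape = c(6, 6, 6), spacing_mm = 6,
                            seed = 1, conductivity_s_m = 0.33) {
  stopifnot(n_sensors >= 8, length(grid_shape) == 3, spacing_mm > 0)
  if (prod(grid_shape) < 27) stop("grid must contain at least 27 voxels")

  grid <- make_source_grid(grid_shape, spacing_mm)

  shell_r <- max(sqrt(rowSums(grid$coords^2))) + 25
  with_seed(seed, {
    for (try in seq_len(100)) {
      pos <- fibonacci_hemisphere(n_sensors, shell_r)
      # small jitter keeps degenerate symmetric layouts away from the
      # dipole formula's singularities
      pos <- pos + matrix(stats::rnorm(3 * n_sensors, sd = 0.5), ncol = 3)
      d <- min(cross_dist(pos, grid$coords))
      if (d > spacing_mm / 2) break
      if (try == 100) stop("could not place sensors clear of the source grid")
    }
    lf <- dipole_leadfield(pos, grid$coords, conductivity_s_m)
    lf <- sweep(lf, 2, colMeans(lf))   # average reference: columns sum to 0
    list(
      grid = grid,
      leadfield = structure(
        list(matrix = lf, sensor_positions = pos, reference = "average"),
        class = "leadfield")
    )
  })
}

make_source_grid <- function(grid_shape, spacing_mm, gm_mask = NULL) {
  ax <- lapply(grid_shape, function(k) (seq_len(k) - (k + 1) / 2) * spacing_mm)
  coords <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  dimnames(coords) <- NULL
  n <- nrow(coords)
  # gray matter = the upper portion of the volume, i.e. the part of the
  # grid under the sensor array, standing in for cortex under a head net
  if (is.null(gm_mask)) gm_mask <- coords[, 3] >= stats::quantile(ax[[3]], 0.3)
  structure(list(coords = coords, spacing = spacing_mm, gm_mask = gm_mask,
                 n_voxels = n, shape = as.integer(grid_shape)),
            class = "source_grid")
}

# quasi-uniform points on the upper hemisphere (z >= 0) of radius r
fibonacci_hemisphere <- function(n, r) {
  i <- seq_len(n) - 0.5
  z <- i / n                      # cos(theta) in (0, 1): upper hemisphere
  phi <- pi * (1 + sqrt(5)) * i
  s <- sqrt(1 - z^2)
  r * cbind(s * cos(phi), s * sin(phi), z)
}

cross_dist <- function(a, b) {
  aa <- rowSums(a^2); bb <- rowSums(b^2)
  d2 <- outer(aa, bb, `+`) - 2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}

# potential of unit current dipoles (3 orthogonal moments per source) in an
# infinite homogeneous conductor: V = q . (r - r0) / (4 pi sigma |r - r0|^3)
dipole_leadfield <- function(sensor_pos, source_pos, sigma = 0.33) {
  n_s <- nrow(sensor_pos); n_v <- nrow(source_pos)
  lf <- matrix(0, n_s, 3 * n_v)
  for (v in seq_len(n_v)) {
    dr <- sweep(sensor_pos, 2, source_pos[v, ])
    r3 <- rowSums(dr^2)^1.5
    lf[, (3 * v - 2):(3 * v)] <- dr / (4 * pi * sigma * r3)
  }
  lf
}
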