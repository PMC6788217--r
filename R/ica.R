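#' MDL model-order selection from covariance eigenvalues
#'
#' Wax-Kailath minimum description length criterion on the eigenvalues of
#' the sample covariance of `data_matrix` (rows = variables, columns =
#' observations). Returns the number of signal components `k` minimizing
#' MDL(k) over `0 <= k < rank`.
#'
#' The criterion is scale invariant: multiplying the data by a constant does
#' not change the selected order.
#'
#' @param data_matrix numeric matrix, variables x observations.
#' @return integer model order.
#' @export
estimate_order_mdl <- function(data_matrix) {
  x <- as.matrix(data_matrix)
  dim_p <- nrow(x)
  n <- ncol(x)
  xc <- x - rowMeans(x)
  ev <- eigen(tcrossprod(xc) / n, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  # evaluate only below the covariance rank
  rank <- sum(ev > max(ev) * 1e-12)
  ks <- 0:(rank - 1)
  mdl <- vapply(ks, function(k) {
    tail_ev <- ev[(k + 1):dim_p]
    tail_ev <- tail_ev[tail_ev > 0]
    m <- length(tail_ev)
    gm <- exp(mean(log(tail_ev)))
    am <- mean(tail_ev)
    -n * m * log(gm / am) + 0.5 * k * (2 * dim_p - k) * log(n)
  }, numeric(1))
  ks[which.min(mdl)]
}

#' FastICA by deflation with tanh nonlinearity
#'
#' PCA-whitens `data_matrix` (rows = mixed signals, columns = observations)
#' to `k` dimensions, then extracts independent components one at a time
#' with the fixed-point tanh update and Gram-Schmidt decorrelation against
#' previously found components. A component that fails to converge is
#' restarted from a fresh random direction up to `n_restarts` times.
#' Deterministic given `seed`.
#'
#' Each component's sign is fixed so that its mixing (loading) column has
#' positive skewness, falling back to making its largest-magnitude entry
#' positive; this makes downstream template matching reproducible.
#'
#' @param data_matrix numeric matrix, signals x observations.
#' @param k number of components (<= rank of the data).
#' @param seed integer seed for the random initial directions.
#' @param tol convergence tolerance on the direction update.
#' @param max_iter maximum fixed-point iterations per component.
#' @param n_restarts restarts allowed for a non-converging component.
#' @return object of class `ic_decomposition`: `k`, `whitening` (k x dim),
#'   `mixing` (dim x k), `sources` (k x n, unit variance rows),
#'   `row_means`, `convergence` (iterations per component), `seed`.
#' @export
fastica_deflation <- function(data_matrix, k, seed = 1, tol = 1e-4,
                              max_iter = 1000, n_restarts = 10) {
  x <- as.matrix(data_matrix)
  if (!all(is.finite(x))) stop("data contains non-finite values")
  dim_p <- nrow(x)
  n <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  eg <- eigen(tcrossprod(xc) / n, symmetric = TRUE)
  rank <- sum(eg$values > max(eg$values, 0) * 1e-10)
  if (k > rank) stop("k exceeds the rank of the data (rank ", rank, ")")
  d <- eg$values[seq_len(k)]
  e <- eg$vectors[, seq_len(k), drop = FALSE]
  whitening <- diag(1 / sqrt(d), k) %*% t(e)
  dewhitening <- e %*% diag(sqrt(d), k)
  z <- whitening %*% xc                      # k x n, identity covariance

  w_all <- matrix(0, k, k)
  iters <- integer(k)
  with_seed(seed, {
    for (p in seq_len(k)) {
      ok <- FALSE
      for (restart in 0:n_restarts) {
        w <- stats::rnorm(k)
        if (p > 1) {
          prev <- w_all[seq_len(p - 1), , drop = FALSE]
          w <- w - t(prev) %*% (prev %*% w)
        }
        w <- w / sqrt(sum(w^2))
        mu <- 1                            # damped (stabilized) updates are
        for (it in seq_len(max_iter)) {    # enabled if plain ones oscillate
          wx <- as.numeric(crossprod(w, z))
          g <- tanh(wx)
          gp <- 1 - g^2
          w_new <- z %*% g / n - mean(gp) * w
          if (mu < 1) w_new <- w + mu * (w_new - w)
          if (p > 1) {
            prev <- w_all[seq_len(p - 1), , drop = FALSE]
            w_new <- w_new - t(prev) %*% (prev %*% w_new)
          }
          nw <- sqrt(sum(w_new^2))
          if (nw < 1e-12) break            # collapsed into previous span
          w_new <- w_new / nw
          delta <- 1 - abs(sum(w_new * w))
          w <- as.numeric(w_new)
          if (delta < tol) { ok <- TRUE; iters[p] <- it; break }
          if (it == max_iter %/% 2) mu <- 0.5
        }
        if (ok) break
      }
      if (!ok) stop("FastICA component ", p, " failed to converge after ",
                    n_restarts, " restarts")
      w_all[p, ] <- w
    }
  })

  sources <- w_all %*% z
  # exact unit variance rows
  sds <- sqrt(rowMeans(sources^2) - rowMeans(sources)^2)
  sources <- sources / sds
  mixing <- dewhitening %*% t(w_all) * rep(sds, each = nrow(dewhitening))
  # sign convention: positive skewness of the loading column
  for (p in seq_len(k)) {
    a <- mixing[, p]
    sk <- mean((a - mean(a))^3)
    flip <- if (abs(sk) > 1e-12 * stats::sd(a)^3) sk < 0 else
      a[which.max(abs(a))] < 0
    if (flip) { mixing[, p] <- -a; sources[p, ] <- -sources[p, ] }
  }
  structure(list(k = k, whitening = whitening, mixing = mixing,
                 sources = sources, row_means = mu,
                 convergence = iters, seed = seed),
            class = "ic_decomposition")
}

# numerical rank of the row-centered data (same tolerance as the
# whitening step of fastica_deflation)
data_rank <- function(x) {
  x <- as.matrix(x)
  xc <- x - rowMeans(x)
  g <- if (nrow(xc) <= ncol(xc)) tcrossprod(xc) else crossprod(xc)
  ev <- eigen(g, symmetric = TRUE, only.values = TRUE)$values
  sum(ev > max(ev, 0) * 1e-10)
}

#' Amari index between an estimated and a true mixing matrix
#'
#' Permutation- and scale-invariant distance used to score blind source
#' separation: 0 for a perfect recovery (up to permutation/sign/scale),
#' larger for worse. Computed from `P = solve(est_mixing) %*% true_mixing`.
#'
#' @param est_mixing,true_mixing square mixing matrices.
#' @return nonnegative scalar.
#' @export
amari_index <- function(est_mixing, true_mixing) {
  p <- solve(est_mixing) %*% true_mixing
  p <- abs(p)
  k <- nrow(p)
  row_term <- sum(rowSums(p / apply(p, 1, max)) - 1)
  col_term <- sum(colSums(t(t(p) / apply(p, 2, max))) - 1)
  (row_term + col_term) / (2 * k * (k - 1))
}
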