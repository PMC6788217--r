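#' Canonical EEG frequency bands
#'
#' Band edges in Hz for the six analysis bands: delta (1-4), theta (4-8),
#' alpha (8-13), beta (13-30), gamma (30-80) and full (1-80). Edges are
#' half-open `[lo, hi)` so that a shared printed edge belongs to the higher
#' band (13 Hz is beta, 8 Hz is alpha); gamma and full close at 80 Hz
#' inclusive.
#'
#' @return A data.frame with columns `band`, `f_lo`, `f_hi`.
#' @export
eeg_bands <- function() {
  data.frame(
    band = c("full", "delta", "theta", "alpha", "beta", "gamma"),
    f_lo = c(1, 1, 4, 8, 13, 30),
    f_hi = c(80, 4, 8, 13, 30, 80),
    stringsAsFactors = FALSE
  )
}

band_edges <- function(band) {
  b <- eeg_bands()
  i <- match(band, b$band)
  if (is.na(i)) stop("unknown band: ", band)
  c(b$f_lo[i], b$f_hi[i])
}

#' Evaluate an expression with a local RNG seed
#'
#' Sets the RNG to `seed`, evaluates `expr`, and restores the previous RNG
#' state on exit, so generators are pure functions of (config, seed) without
#' perturbing the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# power ratio in decibel
db_ratio <- function(p_num, p_den) 10 * log10(p_num / p_den)

#' Short-time Fourier power of a single trace
#'
#' 2 s Hamming window, 50% overlap: one frame per second, the first frame
#' centered at t = 1 s. Power is returned at 1 Hz frequency steps (integer
#' frequencies only), as one-sided periodogram values.
#'
#' @param x numeric trace.
#' @param fs sampling rate (Hz).
#' @param window_s window length in seconds (default 2).
#' @return list with `power` (n_freq x n_frames), `freqs` (Hz, integer
#'   steps), `times` (frame centers, s).
#' @export
stft_power <- function(x, fs, window_s = 2) {
  win <- round(window_s * fs)
  hop <- win %/% 2
  n <- length(x)
  if (n < win) stop("trace shorter than one window")
  n_frames <- (n - win) %/% hop + 1L
  w <- signal::hamming(win)
  idx <- outer(seq_len(win), (seq_len(n_frames) - 1L) * hop, `+`)
  frames <- matrix(x[idx], nrow = win) * w
  spec <- stats::mvfft(frames)
  # one-sided periodogram, 1/(fs * sum(w^2)) scaling
  pg <- (Mod(spec)^2) / (fs * sum(w^2))
  freqs_all <- (seq_len(win) - 1L) * fs / win
  keep <- freqs_all <= fs / 2
  pg <- pg[keep, , drop = FALSE]
  freqs_all <- freqs_all[keep]
  pg[-1, ] <- 2 * pg[-1, ]
  # integer-Hz bins only (band power is defined at 1 Hz steps)
  step <- which(abs(freqs_all - round(freqs_all)) < 1e-9 & freqs_all >= 1)
  list(power = pg[step, , drop = FALSE],
       freqs = freqs_all[step],
       times = window_s / 2 + (seq_len(n_frames) - 1L) * hop / fs)
}

# mean band power per frame from an stft_power() result; half-open [lo, hi)
# except hi = 80 which is inclusive
band_mean_power <- function(sp, f_lo, f_hi, aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  sel <- sp$freqs >= f_lo & (sp$freqs < f_hi | (f_hi >= 80 & sp$freqs == 80))
  if (!any(sel)) stop("no frequency bins in band [", f_lo, ", ", f_hi, ")")
  m <- sp$power[sel, , drop = FALSE]
  if (aggregate == "mean") colMeans(m) else colSums(m)
}

# Pearson correlation that maps zero-variance inputs to 0 (with a warning
# from callers where the convention matters)
safe_cor <- function(x, y) {
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (!is.finite(sx) || !is.finite(sy) || sx == 0 || sy == 0) return(0)
  stats::cor(x, y)
}

#' Fisher r-to-z transform
#'
#' `z = atanh(r)` with `|r|` clipped to `1 - 1e-12` so the transform stays
#' finite for degenerate perfect correlations.
#'
#' @param r correlation value(s).
#' @return transformed value(s).
#' @export
fisher_z <- function(r) {
  r <- pmax(pmin(r, 1 - 1e-12), -1 + 1e-12)
  atanh(r)
}

# column-wise Pearson correlation of a vector with each row of a matrix
row_cor <- function(mat, v) {
  v <- as.numeric(v)
  vc <- v - mean(v)
  sv <- sqrt(sum(vc^2))
  mc <- mat - rowMeans(mat)
  sm <- sqrt(rowSums(mc^2))
  r <- as.numeric(mc %*% vc)
  out <- numeric(nrow(mat))
  ok <- sm > 0 & sv > 0
  out[ok] <- r[ok] / (sm[ok] * sv)
  out
}
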