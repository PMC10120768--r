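# Circular-track helpers shared across modules. All bin indices are 1-based;
# bins 1 and n_bins are spatially adjacent (both lie inside the tunnel).

#' Circular distance between bin indices
#'
#' @param a,b 1-based bin indices (vectors recycle).
#' @param n_bins number of bins on the track.
#' @return Nonnegative distance in bins, at most `n_bins / 2`.
#' @keywords internal
circ_dist_bins <- function(a, b, n_bins) {
  d <- abs(a - b) %% n_bins
  pmin(d, n_bins - d)
}

#' Signed circular difference a - b in cm on a track of length `len`
#'
#' Result lies in (-len/2, len/2]; positive means `a` is ahead of `b` in the
#' running direction.
#' @keywords internal
circ_diff_cm <- function(a, b, len) {
  d <- (a - b) %% len
  ifelse(d > len / 2, d - len, d)
}

#' Bins within a circular window around a center bin
#'
#' @param center 1-based center bin.
#' @param halfwidth_bins bins on each side to include.
#' @keywords internal
circ_window_bins <- function(center, halfwidth_bins, n_bins) {
  ((center - halfwidth_bins - 1):(center + halfwidth_bins - 1)) %% n_bins + 1L
}

#' Circular sequence of bins from `start` to `end` (inclusive, forward)
#' @keywords internal
circ_span_bins <- function(start, end, n_bins) {
  len <- (end - start) %% n_bins + 1L
  (start + seq_len(len) - 2L) %% n_bins + 1L
}

#' Circular convolution with a normalized Hanning window
#'
#' The window is `0.5 - 0.5 * cos(2 * pi * k / (w - 1))`, k = 0..w-1,
#' normalized to unit sum; `w = 5` matches the field-detection smoothing.
#' NA entries are treated as missing: the kernel is renormalized over the
#' non-missing support so occupancy gaps do not drag the trace to zero.
#'
#' @param x numeric vector (one value per bin).
#' @param width odd window length in bins.
#' @return Smoothed vector of the same length.
#' @keywords internal
hann_smooth_circular <- function(x, width = 5L) {
  n <- length(x)
  if (width <= 1L || n < 3L) return(x)
  k <- seq_len(width) - 1L
  w <- 0.5 - 0.5 * cos(2 * pi * k / (width - 1))
  w <- w / sum(w)
  half <- (width - 1L) %/% 2L
  idx <- outer(seq_len(n), -half:half, function(i, o) (i + o - 1L) %% n + 1L)
  vals <- matrix(x[idx], nrow = n)
  wm <- matrix(w, nrow = n, ncol = width, byrow = TRUE)
  wm[is.na(vals)] <- 0
  vals[is.na(vals)] <- 0
  out <- rowSums(vals * wm) / rowSums(wm)
  out[rowSums(wm) == 0] <- NA_real_
  out
}

#' Circular Gaussian smoothing of a bins-long vector
#' @keywords internal
gauss_smooth_circular <- function(x, sigma_bins) {
  n <- length(x)
  if (sigma_bins <= 0) return(x)
  half <- min(n %/% 2, max(1L, ceiling(3 * sigma_bins)))
  off <- -half:half
  w <- exp(-off^2 / (2 * sigma_bins^2))
  w <- w / sum(w)
  idx <- outer(seq_len(n), off, function(i, o) (i + o - 1L) %% n + 1L)
  vals <- matrix(x[idx], nrow = n)
  wm <- matrix(w, nrow = n, ncol = length(off), byrow = TRUE)
  wm[is.na(vals)] <- 0
  vals[is.na(vals)] <- 0
  rowSums(vals * wm) / pmax(rowSums(wm), .Machine$double.eps)
}

#' Circular center of mass of weighted bins, in cm
#'
#' Computes the vector-mean angle of bin centers weighted by `w` and converts
#' back to track coordinates; immune to the bin-1/bin-n seam.
#'
#' @param bins 1-based bin indices.
#' @param w nonnegative weights (NA treated as 0).
#' @param n_bins,track_length track geometry.
#' @return COM position in cm, in `[0, track_length)`, or NA if all weights
#'   vanish.
#' @keywords internal
circ_com_cm <- function(bins, w, n_bins, track_length) {
  w[is.na(w) | w < 0] <- 0
  if (sum(w) <= 0) return(NA_real_)
  theta <- 2 * pi * (bins - 0.5) / n_bins
  ang <- atan2(sum(w * sin(theta)), sum(w * cos(theta)))
  (ang %% (2 * pi)) / (2 * pi) * track_length
}

#' Trailing rolling minimum over a window of `w` samples
#'
#' Window is `(t - w, t]` inclusive of the current sample; truncated at the
#' start of the trace. Sparse-table doubling keeps it O(n log w).
#' @keywords internal
roll_min_trailing <- function(x, w) {
  n <- length(x)
  if (w <= 1L || n == 0L) return(x)
  w <- min(w, n)
  lag_inf <- function(v, k) c(rep(Inf, k), v[seq_len(n - k)])
  m <- x
  k <- 1L
  while (k * 2L <= w) {
    m <- pmin(m, lag_inf(m, k))
    k <- k * 2L
  }
  if (k < w) m <- pmin(m, lag_inf(m, w - k))
  m
}

#' Centered rolling mean with edge truncation
#'
#' Window of `w` samples centered on each point (w forced odd); edges use the
#' available partial window.
#' @keywords internal
roll_mean_centered <- function(x, w) {
  n <- length(x)
  if (w <= 1L || n == 0L) return(x)
  if (w %% 2L == 0L) w <- w + 1L
  half <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  hi <- pmin(n, seq_len(n) + half)
  lo <- pmax(0L, seq_len(n) - half - 1L)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

#' Position to 1-based bin index
#' @keywords internal
position_to_bin <- function(position, track_length, n_bins) {
  b <- floor((position %% track_length) / (track_length / n_bins)) + 1L
  pmin(as.integer(b), n_bins)
}
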