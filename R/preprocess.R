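# Pre-processing: neuropil-corrected dF/F with a running-minimum baseline,
# and velocity-gated, occupancy-normalized position binning.

#' Preprocessing configuration
#'
#' @param neuropil_coeff neuropil subtraction coefficient in `[0, 1]`
#'   (default 0.7): `F = F_soma - 0.7 * F_neuropil`.
#' @param t1 running-average smoothing window in seconds (default 1), used
#'   only for the baseline; centered (config-switchable via `t1_centered`).
#' @param t2 trailing-minimum window in seconds (default 15): the baseline
#'   `F0(t)` is the minimum of the smoothed trace over `(t - t2, t]`.
#' @param t1_centered logical; centered (default) or trailing running mean.
#' @param speed_floor velocity gate in cm/s (default 1): samples slower than
#'   this are dropped from both signal and occupancy so stationary periods
#'   are never analyzed.
#' @param n_bins position bins per track (default 100).
#' @param drop_partial_laps drop incomplete first/last laps of each
#'   environment block (default TRUE).
#' @return A list of class `PreprocessConfig`.
#' @export
preprocess_config <- function(neuropil_coeff = 0.7, t1 = 1, t2 = 15,
                              t1_centered = TRUE, speed_floor = 1,
                              n_bins = 100L, drop_partial_laps = TRUE) {
  stopifnot(neuropil_coeff >= 0, neuropil_coeff <= 1, t1 <= t2,
            speed_floor >= 0, n_bins >= 2)
  structure(list(neuropil_coeff = neuropil_coeff, t1 = t1, t2 = t2,
                 t1_centered = t1_centered, speed_floor = speed_floor,
                 n_bins = as.integer(n_bins),
                 drop_partial_laps = drop_partial_laps),
            class = "PreprocessConfig")
}

#' Neuropil-corrected dF/F with a running-minimum baseline
#'
#' Per cell: `F = F_soma - neuropil_coeff * F_neuropil`; the trace is
#' smoothed with a running mean over `t1`, the baseline `F0(t)` is the
#' minimum of the smoothed trace within the trailing window `(t - t2, t]`,
#' and `dFF = (F - F0) / F0` with `F0` floored at a small positive epsilon
#' (1e-6 times the 95th percentile of `F` over the session) so flat or
#' all-zero traces yield exactly zero.
#'
#' @param fluo_soma cells x samples soma fluorescence.
#' @param fluo_neuropil optional cells x samples neuropil fluorescence.
#' @param cfg a [preprocess_config()].
#' @param frame_rate_hz sampling rate in Hz.
#' @return cells x samples dF/F matrix. Cells whose floored baseline was hit
#'   anywhere are flagged in attribute `"flagged_cells"` with a warning.
#' @export
compute_dff <- function(fluo_soma, fluo_neuropil = NULL,
                        cfg = preprocess_config(), frame_rate_hz) {
  stopifnot(is.matrix(fluo_soma), frame_rate_hz > 0)
  w2 <- as.integer(round(cfg$t2 * frame_rate_hz))
  if (w2 < 1L) stop("configuration error: t2 is shorter than one frame")
  w1 <- max(1L, as.integer(round(cfg$t1 * frame_rate_hz)))
  f <- fluo_soma
  if (!is.null(fluo_neuropil)) f <- f - cfg$neuropil_coeff * fluo_neuropil
  out <- matrix(0, nrow(f), ncol(f))
  flagged <- logical(nrow(f))
  for (i in seq_len(nrow(f))) {
    x <- f[i, ]
    sm <- if (cfg$t1_centered) roll_mean_centered(x, w1) else {
      cs <- cumsum(c(0, x))
      lo <- pmax(0L, seq_along(x) - w1)
      (cs[seq_along(x) + 1L] - cs[lo + 1L]) / (seq_along(x) - lo)
    }
    f0 <- roll_min_trailing(sm, w2)
    eps <- 1e-6 * stats::quantile(x, 0.95, names = FALSE)
    if (!is.finite(eps) || eps <= 0) eps <- 1e-6
    flagged[i] <- any(f0 < eps)
    out[i, ] <- (x - f0) / pmax(f0, eps)
  }
  if (any(flagged))
    warning(sprintf("compute_dff: %d cell(s) hit the baseline floor", sum(flagged)))
  attr(out, "flagged_cells") <- which(flagged)
  out
}

#' Per-environment sample selection used by binning and decoding
#'
#' Applies the velocity gate, restricts to one environment, optionally drops
#' incomplete first/last laps (a lap is complete if its pre-gated samples
#' reach both the first and the last few bins of the track), and renumbers
#' laps 1..M within the environment.
#'
#' @return List: `idx` (sample indices into the session), `lap_local`,
#'   `bin`, `dt` (seconds credited to each sample), `lap_ids` (original lap
#'   indices kept), `n_laps`.
#' @keywords internal
select_samples <- function(rec, env, cfg = preprocess_config()) {
  stopifnot(inherits(env, "EnvironmentSpec"))
  n <- length(rec$time)
  dt <- c(diff(rec$time), 1 / rec$frame_rate_hz)
  in_env <- rec$env == env$name
  bins_all <- position_to_bin(rec$position, env$track_length, env$n_bins)
  lap_ids <- sort(unique(rec$lap[in_env]))
  if (cfg$drop_partial_laps && length(lap_ids) > 2L) {
    complete <- vapply(lap_ids, function(l) {
      b <- bins_all[in_env & rec$lap == l]
      min(b) <= 3L && max(b) >= env$n_bins - 2L
    }, logical(1))
    # only the first and last lap of the block may be dropped
    keep <- complete | !(lap_ids %in% lap_ids[c(1, length(lap_ids))])
    lap_ids <- lap_ids[keep]
  }
  keep <- which(in_env & rec$velocity >= cfg$speed_floor & rec$lap %in% lap_ids)
  lap_local <- match(rec$lap[keep], lap_ids)
  list(idx = keep, lap_local = lap_local, bin = bins_all[keep],
       dt = dt[keep], lap_ids = lap_ids, n_laps = length(lap_ids))
}

#' Occupancy-normalized position binning of cell activity
#'
#' Builds the laps x bins x cells rate tensor for one environment: samples
#' slower than the speed floor are removed from both numerator and
#' occupancy, then for every (lap, bin) the accumulated signal is divided by
#' the time spent there: dF/F (a level) is time-averaged,
#' `sum(dff * dt) / sum(dt)`, while deconvolved events (counts per frame)
#' become an event rate, `sum(events) / sum(dt)` in events/s. Entries with
#' zero occupancy are NA.
#'
#' @param rec a `SessionRecording`.
#' @param env an `EnvironmentSpec` (with `rec$env` labels matching
#'   `env$name`).
#' @param cfg a [preprocess_config()].
#' @param signal_kind `"dff"` or `"deconv"`. If `"deconv"` is requested but
#'   absent, the positive part of the dF/F first difference is used as a
#'   documented fallback (with a message).
#' @return A `BinnedActivity` list: `rate` (laps x bins x cells),
#'   `occupancy` (laps x bins, seconds), `p_i` (occupancy probability per
#'   bin), `bin_size` (cm), `signal_kind`, `env` (name), `track_length`,
#'   `lap_ids`, `n_laps`, `n_cells`.
#' @export
bin_activity <- function(rec, env, cfg = preprocess_config(),
                         signal_kind = c("dff", "deconv")) {
  signal_kind <- match.arg(signal_kind)
  sig <- get_signal(rec, signal_kind)
  sel <- select_samples(rec, env, cfg)
  acc <- bin_accumulate(t(sig[, sel$idx, drop = FALSE]), sel, env$n_bins,
                        as_counts = signal_kind == "deconv")
  empty_laps <- which(rowSums(acc$occ) == 0)
  if (length(empty_laps))
    message(sprintf("bin_activity: %d lap(s) with no retained samples", length(empty_laps)))
  tot <- colSums(acc$occ)
  structure(list(
    rate = acc$rate, occupancy = acc$occ,
    p_i = if (sum(tot) > 0) tot / sum(tot) else tot,
    bin_size = env$track_length / env$n_bins,
    signal_kind = signal_kind, env = env$name,
    track_length = env$track_length,
    lap_ids = sel$lap_ids, n_laps = sel$n_laps, n_cells = dim(acc$rate)[3]
  ), class = "BinnedActivity")
}

# shared accumulation core: values is samples x k matrix aligned with sel;
# index runs bin-fastest within lap so the flat vector reshapes to
# (bin, lap) column-major. Level signals (dF/F, velocity) are time-averaged
# (sum x*dt / sum dt); count signals (deconvolved events per frame) are
# summed and divided by occupancy, yielding events per second.
bin_accumulate <- function(values, sel, n_bins, as_counts = FALSE) {
  m <- sel$n_laps
  k <- ncol(values)
  idx <- (sel$lap_local - 1L) * n_bins + sel$bin
  occ_v <- numeric(m * n_bins)
  oc <- rowsum(sel$dt, idx)
  occ_v[as.integer(rownames(oc))] <- oc[, 1]
  sum_m <- matrix(0, m * n_bins, k)
  if (nrow(values) > 0) {
    sums <- rowsum(if (as_counts) values else values * sel$dt, idx)
    sum_m[as.integer(rownames(sums)), ] <- sums
  }
  rate_m <- sum_m / ifelse(occ_v > 0, occ_v, NA_real_)
  rate <- aperm(array(rate_m, dim = c(n_bins, m, k)), c(2, 1, 3))
  occ <- t(matrix(occ_v, n_bins, m))
  list(rate = rate, occ = occ)
}

get_signal <- function(rec, signal_kind) {
  if (signal_kind == "dff") {
    if (is.null(rec$dff)) stop("bin_activity: dff channel absent; run compute_dff first")
    rec$dff
  } else {
    if (!is.null(rec$deconv)) rec$deconv else {
      if (is.null(rec$dff)) stop("bin_activity: neither deconv nor dff present")
      message("bin_activity: deconv absent; using positive part of dF/F first difference")
      d <- cbind(0, t(apply(rec$dff, 1, diff)))
      pmax(d, 0)
    }
  }
}

#' Occupancy-normalized binning of a per-sample scalar signal
#'
#' Same velocity gating and lap selection as [bin_activity()], for a single
#' vector such as running speed. Used for the speed-at-peak control.
#'
#' @inheritParams bin_activity
#' @param values numeric vector, one value per session sample.
#' @return laps x bins matrix (NA where unoccupied).
#' @export
bin_signal <- function(rec, env, values, cfg = preprocess_config()) {
  stopifnot(length(values) == length(rec$time))
  sel <- select_samples(rec, env, cfg)
  acc <- bin_accumulate(matrix(values[sel$idx], ncol = 1), sel, env$n_bins)
  matrix(acc$rate[, , 1], sel$n_laps, env$n_bins)
}
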