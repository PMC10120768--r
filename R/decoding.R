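# Bayesian population decoding of position with leave-one-lap-out
# cross-validation.

#' Decoder configuration
#'
#' @param tau decoding window length in seconds (default 3).
#' @param ratemap_smooth_sigma circular Gaussian smoothing of the per-bin
#'   training rates, in bins (default 2).
#' @param error_threshold threshold for the per-lap error-exceedance
#'   fraction, cm (default 20).
#' @param rate_floor_events floor applied to smoothed rates, expressed in
#'   expected events per window: `f >= rate_floor_events / tau` (default
#'   0.01), keeping the log-likelihood finite.
#' @param circular_error use the circular distance `min(d, L - d)` (default)
#'   or the literal linear `|d|`.
#' @param min_window_frac trailing windows shorter than this fraction of
#'   `tau` are dropped (default 0.5).
#' @return A list of class `DecoderConfig`.
#' @export
decoder_config <- function(tau = 3, ratemap_smooth_sigma = 2,
                           error_threshold = 20, rate_floor_events = 0.01,
                           circular_error = TRUE, min_window_frac = 0.5) {
  stopifnot(tau > 0, ratemap_smooth_sigma >= 0)
  structure(list(tau = tau, ratemap_smooth_sigma = ratemap_smooth_sigma,
                 error_threshold = error_threshold,
                 rate_floor_events = rate_floor_events,
                 circular_error = circular_error,
                 min_window_frac = min_window_frac),
            class = "DecoderConfig")
}

#' Leave-one-lap-out Bayesian position decoding
#'
#' For each lap, per-cell tuning curves `f_i(x)` are the Gaussian-smoothed
#' (circular, sigma bins) mean rates over all *other* laps. Retained
#' (velocity-gated) samples of the decoded lap are cut into non-overlapping
#' windows of `tau` seconds (truncated at the lap boundary); with `n_i` the
#' summed events of cell i in a window of duration `T`, the log posterior
#' under a Poisson likelihood and uniform prior is
#' `sum_i n_i log f_i(x) - T sum_i f_i(x)` (normalized across bins). The
#' decoded position is the posterior argmax; the error is the circular
#' distance to the true position at the window midpoint.
#'
#' @param rec a `SessionRecording` with a deconvolved (or fallback) event
#'   channel.
#' @param env an `EnvironmentSpec`.
#' @param cfg a [decoder_config()].
#' @param pre_cfg a [preprocess_config()] (velocity gate, lap selection).
#' @param loocv set FALSE to train on all laps including the decoded one
#'   (sanity baseline; default TRUE).
#' @param keep_posterior return the windows x bins posterior matrix.
#' @return A `DecoderOutput` list: `windows` (data.frame: lap, t_mid,
#'   duration, decoded_bin, true_bin, error_cm), `laps` (data.frame: lap,
#'   mean_error_cm, frac_above_threshold, n_windows, duration), `mean_error_cm`,
#'   `best5_error_cm`, `posterior` (optional), plus geometry fields.
#' @export
decode_loocv <- function(rec, env, cfg = decoder_config(),
                         pre_cfg = preprocess_config(), loocv = TRUE,
                         keep_posterior = FALSE) {
  binned <- bin_activity(rec, env, pre_cfg, signal_kind = "deconv")
  if (binned$n_laps < 3L) stop("decode_loocv: need at least 3 laps")
  sel <- select_samples(rec, env, pre_cfg)
  sig <- get_signal(rec, "deconv")[, sel$idx, drop = FALSE]  # cells x kept samples
  n_bins <- env$n_bins
  bin_size <- env$track_length / n_bins
  floor_rate <- cfg$rate_floor_events / cfg$tau

  # build non-overlapping tau windows within each lap
  win_rows <- list()
  post_rows <- list()
  for (lap in seq_len(binned$n_laps)) {
    smp <- which(sel$lap_local == lap)
    if (!length(smp)) next
    cum <- cumsum(sel$dt[smp])
    # assign each retained sample to a tau-long window by its midpoint in
    # retained time; short trailing windows are dropped below
    wid <- floor((cum - sel$dt[smp] / 2) / cfg$tau) + 1L
    # training ratemap for this lap
    train_laps <- if (loocv) setdiff(seq_len(binned$n_laps), lap) else
      seq_len(binned$n_laps)
    fmap <- apply(binned$rate[train_laps, , , drop = FALSE], c(2, 3), mean,
                  na.rm = TRUE)                      # bins x cells
    fmap[is.nan(fmap)] <- 0
    fmap <- apply(fmap, 2, gauss_smooth_circular,
                  sigma_bins = cfg$ratemap_smooth_sigma)
    fmap <- pmax(fmap, floor_rate)
    logf <- log(fmap)
    fsum <- rowSums(fmap)                            # per bin: sum over cells
    for (w in unique(wid)) {
      ws <- smp[wid == w]
      dur <- sum(sel$dt[ws])
      if (dur < cfg$min_window_frac * cfg$tau) next
      n_i <- rowSums(sig[, ws, drop = FALSE])        # per cell
      loglik <- as.numeric(logf %*% n_i) - dur * fsum
      loglik <- loglik - max(loglik)
      post <- exp(loglik); post <- post / sum(post)
      dec_bin <- which.max(post)
      mid <- ws[ceiling(length(ws) / 2)]
      true_bin <- sel$bin[mid]
      d_bins <- if (cfg$circular_error)
        circ_dist_bins(dec_bin, true_bin, n_bins) else abs(dec_bin - true_bin)
      win_rows[[length(win_rows) + 1L]] <- data.frame(
        lap = lap, t_mid = rec$time[sel$idx[mid]], duration = dur,
        decoded_bin = dec_bin, true_bin = true_bin,
        error_cm = d_bins * bin_size)
      if (keep_posterior) post_rows[[length(post_rows) + 1L]] <- post
    }
  }
  if (!length(win_rows)) stop("decode_loocv: no decodable windows")
  windows <- do.call(rbind, win_rows)
  laps <- do.call(rbind, lapply(split(windows, windows$lap), function(d)
    data.frame(lap = d$lap[1],
               mean_error_cm = sum(d$error_cm * d$duration) / sum(d$duration),
               frac_above_threshold =
                 sum(d$duration[d$error_cm > cfg$error_threshold]) / sum(d$duration),
               n_windows = nrow(d), duration = sum(d$duration))))
  rownames(laps) <- NULL
  out <- structure(list(
    windows = windows, laps = laps,
    mean_error_cm = mean(laps$mean_error_cm),
    best5_error_cm = best_laps_error_from(laps, 5L),
    track_length = env$track_length, n_bins = n_bins,
    error_threshold = cfg$error_threshold, env = env$name
  ), class = "DecoderOutput")
  if (keep_posterior) out$posterior <- do.call(rbind, post_rows)
  out
}

best_laps_error_from <- function(laps, k) {
  errs <- sort(laps$mean_error_cm)
  mean(errs[seq_len(min(k, length(errs)))])
}

#' Mean decoder error over the best k laps
#'
#' @param out a `DecoderOutput`.
#' @param k number of laps (default 5); if fewer laps were decoded, all are
#'   used with a message.
#' @return Mean of the k smallest per-lap mean errors, cm.
#' @export
best_laps_error <- function(out, k = 5L) {
  if (nrow(out$laps) < k)
    message("best_laps_error: fewer laps than k; using all laps")
  best_laps_error_from(out$laps, k)
}

#' Per-lap fraction of time with decoder error above a threshold
#'
#' The lap-indexed series behind the across-lap learning-curve regression:
#' for each lap, the time-weighted fraction of decoding windows whose error
#' exceeds `threshold` (20 cm, i.e. 3-6 bins depending on track length).
#'
#' @param out a `DecoderOutput`.
#' @param threshold cm (default 20).
#' @return data.frame with `lap` and `frac_above`.
#' @export
error_exceedance_by_lap <- function(out, threshold = 20) {
  d <- out$windows
  res <- do.call(rbind, lapply(split(d, d$lap), function(x)
    data.frame(lap = x$lap[1],
               frac_above = sum(x$duration[x$error_cm > threshold]) /
                 sum(x$duration))))
  rownames(res) <- NULL
  res
}
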