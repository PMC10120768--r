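# Population-vector correlations and lap-wise field dynamics.

# cellwise mean rate per bin over a lap window -> bins x cells matrix
pv_set <- function(binned, laps) {
  m <- apply(binned$rate[laps, , , drop = FALSE], c(2, 3), mean, na.rm = TRUE)
  m[is.nan(m)] <- NA_real_
  m
}

#' Population-vector correlation matrix between two lap sets
#'
#' A population vector (PV) is the vector of all cells' rates at one
#' position bin, averaged over a window of consecutive laps (3 by
#' convention). Entry `[b1, b2]` is the Pearson correlation of the PV at bin
#' b1 of the first lap set with the PV at bin b2 of the second; both tensors
#' must share the cell dimension and use 100 bins so matrices are square
#' even across environments of different length. `diag_mean` averages the
#' finite diagonal entries (requires at least `min_finite` of them).
#'
#' @param binned_ref,binned_other `BinnedActivity` tensors sharing cells.
#' @param laps_ref,laps_other lap indices of the two windows (default: first
#'   `lap_window` laps of each).
#' @param lap_window default window length (3 laps).
#' @param min_finite minimum finite diagonal entries for `diag_mean`
#'   (default 50).
#' @return A `PvCorrelation` list: `matrix` (bins x bins), `diag_mean`,
#'   `lap_window`.
#' @export
pv_matrix <- function(binned_ref, binned_other,
                      laps_ref = NULL, laps_other = NULL,
                      lap_window = 3L, min_finite = 50L) {
  stopifnot(dim(binned_ref$rate)[3] == dim(binned_other$rate)[3],
            dim(binned_ref$rate)[2] == dim(binned_other$rate)[2])
  if (is.null(laps_ref)) laps_ref <- seq_len(min(lap_window, binned_ref$n_laps))
  if (is.null(laps_other)) laps_other <- seq_len(min(lap_window, binned_other$n_laps))
  a <- pv_set(binned_ref, laps_ref)     # bins x cells
  b <- pv_set(binned_other, laps_other)
  suppressWarnings(cm <- stats::cor(t(a), t(b), use = "pairwise.complete.obs"))
  dg <- diag(cm)
  fin <- is.finite(dg)
  structure(list(
    matrix = cm,
    diag_mean = if (sum(fin) >= min_finite) mean(dg[fin]) else NA_real_,
    lap_window = lap_window
  ), class = "PvCorrelation")
}

#' PV-correlation timecourses across laps and the teleportation
#'
#' Three standard variants, each a series of diagonal-mean PV correlations
#' over non-overlapping 3-lap intervals:
#' \describe{
#'   \item{`"final_familiar"`}{reference = final 3 familiar laps, compared
#'     with every non-overlapping 3-lap interval across the whole session
#'     (familiar then novel); shows the immediate de-correlation at the
#'     teleportation.}
#'   \item{`"novel_late"`}{reference = novel laps 13-15, compared with the
#'     earlier novel intervals; shows gradual stabilization.}
#'   \item{`"offset7"`}{each novel 3-lap interval versus the interval
#'     starting 7 laps later (laps 1-3 vs 8-10, ...); distinguishes drift
#'     from stabilization.}
#' }
#'
#' @param binned_fam,binned_nov `BinnedActivity` for the two environments
#'   (same cells). `binned_nov` may be NULL for `"offset7"` on a single
#'   environment, in which case `binned_fam` is used.
#' @param variant one of `"final_familiar"`, `"novel_late"`, `"offset7"`.
#' @param lap_window interval length (3).
#' @return data.frame with `env`, `start_lap` (first lap of the compared
#'   interval, local to its environment) and `diag_mean`; attribute
#'   `"skipped"` is TRUE when the variant had too few laps.
#' @export
pv_timecourse <- function(binned_fam, binned_nov = NULL,
                          variant = c("final_familiar", "novel_late", "offset7"),
                          lap_window = 3L) {
  variant <- match.arg(variant)
  empty <- structure(data.frame(env = character(), start_lap = integer(),
                                diag_mean = numeric()), skipped = TRUE)
  starts <- function(m) {
    if (m < lap_window) return(integer())
    seq(1L, m - lap_window + 1L, by = lap_window)
  }
  if (variant == "final_familiar") {
    mf <- binned_fam$n_laps
    if (mf < lap_window || is.null(binned_nov)) {
      message("pv_timecourse: too few laps for final_familiar; skipped")
      return(empty)
    }
    ref <- (mf - lap_window + 1L):mf
    rows <- list()
    for (s in starts(mf))
      rows[[length(rows) + 1L]] <- data.frame(
        env = binned_fam$env, start_lap = s,
        diag_mean = pv_matrix(binned_fam, binned_fam, ref, s:(s + lap_window - 1L))$diag_mean)
    for (s in starts(binned_nov$n_laps))
      rows[[length(rows) + 1L]] <- data.frame(
        env = binned_nov$env, start_lap = s,
        diag_mean = pv_matrix(binned_fam, binned_nov, ref, s:(s + lap_window - 1L))$diag_mean)
    return(do.call(rbind, rows))
  }
  if (variant == "novel_late") {
    b <- if (is.null(binned_nov)) binned_fam else binned_nov
    if (b$n_laps < 15L) {
      message("pv_timecourse: fewer than 15 novel laps; skipped")
      return(empty)
    }
    ref <- 13:15
    rows <- lapply(starts(12L), function(s) data.frame(
      env = b$env, start_lap = s,
      diag_mean = pv_matrix(b, b, ref, s:(s + lap_window - 1L))$diag_mean))
    return(do.call(rbind, rows))
  }
  # offset7: interval s vs interval s + 7
  b <- if (is.null(binned_nov)) binned_fam else binned_nov
  off <- 7L
  last_start <- b$n_laps - off - lap_window + 1L
  ss <- if (last_start >= 1L) seq(1L, last_start, by = lap_window) else integer()
  if (!length(ss)) {
    message("pv_timecourse: too few laps for offset7; skipped")
    return(empty)
  }
  do.call(rbind, lapply(ss, function(s) data.frame(
    env = b$env, start_lap = s,
    diag_mean = pv_matrix(b, b, s:(s + lap_window - 1L),
                          (s + off):(s + off + lap_window - 1L))$diag_mean)))
}

#' Lap-wise z-scored activity of PCC overlap groups
#'
#' Cells are grouped by where they hold fields (familiar-only, both,
#' novel-only). Each cell's per-lap mean activity across the whole session
#' (familiar laps then novel laps) is z-scored over laps, then averaged
#' within groups. Also reports the "both" group's relative rate drop from
#' familiar to novel, measured on the raw (un-z-scored) lap means.
#'
#' @param binned_fam,binned_nov `BinnedActivity` for the two environments.
#' @param pcc_fam,pcc_nov `PccResult`s for the same cells.
#' @return List: `series` (data.frame: env, lap, group, mean_z, n_cells),
#'   `both_drop_frac` (1 - novel/familiar mean rate of the "both" group).
#' @export
group_activity <- function(binned_fam, binned_nov, pcc_fam, pcc_nov) {
  is_f <- pcc_fam$table$is_pcc
  is_n <- pcc_nov$table$is_pcc
  groups <- list(familiar_only = is_f & !is_n, both = is_f & is_n,
                 novel_only = !is_f & is_n)
  lap_mean <- function(binned) {
    lm <- apply(binned$rate, c(1, 3), mean, na.rm = TRUE)   # laps x cells
    lm[is.nan(lm)] <- NA_real_
    lm
  }
  lm_all <- rbind(lap_mean(binned_fam), lap_mean(binned_nov))
  fam_rows <- seq_len(binned_fam$n_laps)
  nov_rows <- binned_fam$n_laps + seq_len(binned_nov$n_laps)
  envs <- c(rep("familiar", binned_fam$n_laps),
            rep("novel", binned_nov$n_laps))
  laps <- c(seq_len(binned_fam$n_laps), seq_len(binned_nov$n_laps))
  z <- scale(lm_all)                                        # z over session laps
  rows <- list()
  for (g in names(groups)) {
    sel <- groups[[g]]
    if (!any(sel)) { message(sprintf("group_activity: empty group %s", g)); next }
    mz <- rowMeans(z[, sel, drop = FALSE], na.rm = TRUE)
    rows[[g]] <- data.frame(env = envs, lap = laps, group = g, mean_z = mz,
                            n_cells = sum(sel))
  }
  both_drop <- NA_real_
  if (any(groups$both)) {
    fam_m <- mean(lm_all[fam_rows, groups$both, drop = FALSE], na.rm = TRUE)
    nov_m <- mean(lm_all[nov_rows, groups$both, drop = FALSE], na.rm = TRUE)
    if (is.finite(fam_m) && fam_m > 0) both_drop <- 1 - nov_m / fam_m
  }
  list(series = do.call(rbind, rows), both_drop_frac = both_drop)
}

#' In-field versus out-of-field activity ratio per lap
#'
#' For every cell (not just PCCs), in-field is the 30 cm circular window
#' centered on the cell's peak of the lap-averaged trace; out-of-field is
#' all other bins. The per-lap ratio of mean in-field to mean out-of-field
#' activity is averaged across cells.
#'
#' @param binned a `BinnedActivity`.
#' @param window_cm in-field window width (default 30 cm).
#' @return data.frame: `lap`, `ratio` (mean over cells with finite ratios),
#'   `n_cells`.
#' @export
in_out_ratio <- function(binned, window_cm = 30) {
  n_bins <- dim(binned$rate)[2]
  half <- max(1L, floor(window_cm / binned$bin_size / 2))
  lapavg <- apply(binned$rate, c(2, 3), mean, na.rm = TRUE)
  lapavg[is.nan(lapavg)] <- 0
  peaks <- apply(lapavg, 2, which.max)
  ratios <- matrix(NA_real_, binned$n_laps, dim(binned$rate)[3])
  for (cellk in seq_len(dim(binned$rate)[3])) {
    wb <- circ_window_bins(peaks[cellk], half, n_bins)
    infield <- rowMeans(binned$rate[, wb, cellk, drop = FALSE], na.rm = TRUE)
    outfield <- rowMeans(binned$rate[, -wb, cellk, drop = FALSE], na.rm = TRUE)
    r <- infield / outfield
    r[!is.finite(r)] <- NA_real_
    ratios[, cellk] <- r
  }
  data.frame(lap = seq_len(binned$n_laps),
             ratio = rowMeans(ratios, na.rm = TRUE),
             n_cells = rowSums(is.finite(ratios)))
}

#' Lap-wise center-of-mass offsets of place fields
#'
#' For each field, the circular COM of the in-boundary activity is computed
#' on every active lap (laps meeting the field's step-2 activity rule,
#' starting at the onset lap) and the field's across-lap mean COM is
#' subtracted; negative offsets are backward shifts. The population mean is
#' indexed by laps since field onset.
#'
#' @param binned a `BinnedActivity`.
#' @param fields list of `PlaceField`s (from [detect_fields()] /
#'   [classify_pcc()]).
#' @return List: `per_field` (data.frame: field, cell, lap,
#'   laps_since_onset, com_offset_cm), `by_lap` (data.frame:
#'   laps_since_onset, mean_offset_cm, n).
#' @export
com_shift <- function(binned, fields) {
  n_bins <- dim(binned$rate)[2]
  rows <- list()
  for (fi in seq_along(fields)) {
    f <- fields[[fi]]
    span <- circ_span_bins(f$start, f$end, n_bins)
    coms <- vapply(f$active_laps, function(l)
      circ_com_cm(span, binned$rate[l, span, f$cell], n_bins,
                  binned$track_length), numeric(1))
    ok <- is.finite(coms)
    if (!any(ok)) next
    # circular mean of the per-lap COMs
    theta <- 2 * pi * coms[ok] / binned$track_length
    mean_com <- (atan2(mean(sin(theta)), mean(cos(theta))) %% (2 * pi)) /
      (2 * pi) * binned$track_length
    rows[[length(rows) + 1L]] <- data.frame(
      field = fi, cell = f$cell, lap = f$active_laps[ok],
      laps_since_onset = f$active_laps[ok] - f$onset_lap,
      com_offset_cm = circ_diff_cm(coms[ok], mean_com, binned$track_length))
  }
  per_field <- if (length(rows)) do.call(rbind, rows) else
    data.frame(field = integer(), cell = integer(), lap = integer(),
               laps_since_onset = integer(), com_offset_cm = numeric())
  by_lap <- if (nrow(per_field)) {
    agg <- stats::aggregate(com_offset_cm ~ laps_since_onset, per_field, mean)
    agg$n <- stats::aggregate(com_offset_cm ~ laps_since_onset, per_field,
                              length)$com_offset_cm
    names(agg)[2] <- "mean_offset_cm"
    agg
  } else data.frame(laps_since_onset = integer(), mean_offset_cm = numeric(),
                    n = integer())
  list(per_field = per_field, by_lap = by_lap)
}

#' Lap-wise place-field size (above-threshold bins within boundaries)
#'
#' For each active lap of each field, counts the bins inside the fixed
#' average-field boundary whose activity exceeds the cell's 50th percentile
#' over all bins and laps, normalized by the field's across-lap mean count.
#'
#' @inheritParams com_shift
#' @return List: `per_field` (field, cell, lap, laps_since_onset, size_bins,
#'   size_norm), `by_lap` (laps_since_onset, mean_size_norm, n).
#' @export
field_size_by_lap <- function(binned, fields) {
  n_bins <- dim(binned$rate)[2]
  rows <- list()
  for (fi in seq_along(fields)) {
    f <- fields[[fi]]
    span <- circ_span_bins(f$start, f$end, n_bins)
    thr <- stats::median(binned$rate[, , f$cell], na.rm = TRUE)
    sizes <- vapply(f$active_laps, function(l)
      sum(binned$rate[l, span, f$cell] > thr, na.rm = TRUE), numeric(1))
    if (mean(sizes) <= 0) next
    rows[[length(rows) + 1L]] <- data.frame(
      field = fi, cell = f$cell, lap = f$active_laps,
      laps_since_onset = f$active_laps - f$onset_lap,
      size_bins = sizes, size_norm = sizes / mean(sizes))
  }
  per_field <- if (length(rows)) do.call(rbind, rows) else
    data.frame(field = integer(), cell = integer(), lap = integer(),
               laps_since_onset = integer(), size_bins = numeric(),
               size_norm = numeric())
  by_lap <- if (nrow(per_field)) {
    agg <- stats::aggregate(size_norm ~ laps_since_onset, per_field, mean)
    agg$n <- stats::aggregate(size_norm ~ laps_since_onset, per_field,
                              length)$size_norm
    names(agg)[2] <- "mean_size_norm"
    agg
  } else data.frame(laps_since_onset = integer(), mean_size_norm = numeric(),
                    n = integer())
  list(per_field = per_field, by_lap = by_lap)
}
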