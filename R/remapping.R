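# Global-remapping statistics across environments and rate-remapping
# variance statistics under object destabilization.

#' Correlation of field locations across two environments
#'
#' Restricted to cells with exactly one field in each environment; Pearson
#' correlation of the familiar versus novel peak bins (linear, matching the
#' conventional scatter; a circular-circular alternative is available).
#' `exclude_tunnel` removes cells whose field peak lies within 5 bins of the
#' beginning or end of the track in either environment — fields at the
#' shared tunnel drive spurious correlation.
#'
#' @param pcc_fam,pcc_nov `PccResult`s on the same cell set.
#' @param exclude_tunnel drop near-tunnel fields (default FALSE).
#' @param tunnel_margin_bins exclusion margin (default 5).
#' @param circular use a circular-circular correlation
#'   (Fisher-Lee) instead of linear Pearson (default FALSE).
#' @return List: `r`, `n`, `p` (two-sided), `peaks` (data.frame of the
#'   paired peak bins). `r` is NA when n < 3.
#' @export
field_location_correlation <- function(pcc_fam, pcc_nov,
                                       exclude_tunnel = FALSE,
                                       tunnel_margin_bins = 5L,
                                       circular = FALSE) {
  single <- function(res) {
    tab <- res$table
    tab$cell[tab$is_pcc & tab$n_fields == 1L]
  }
  cells <- intersect(single(pcc_fam), single(pcc_nov))
  pk <- function(res, cells) res$table$peak_bin[match(cells, res$table$cell)]
  a <- pk(pcc_fam, cells)
  b <- pk(pcc_nov, cells)
  if (exclude_tunnel) {
    n_bins <- 100L
    near <- function(x) x <= tunnel_margin_bins | x > n_bins - tunnel_margin_bins
    keep <- !(near(a) | near(b))
    a <- a[keep]; b <- b[keep]; cells <- cells[keep]
  }
  n <- length(cells)
  if (n < 3L)
    return(list(r = NA_real_, n = n, p = NA_real_,
                peaks = data.frame(cell = cells, fam = a, nov = b)))
  if (circular) {
    ta <- 2 * pi * a / 100; tb <- 2 * pi * b / 100
    num <- sum(sin(ta - mean(ta)) * sin(tb - mean(tb)))
    den <- sqrt(sum(sin(ta - mean(ta))^2) * sum(sin(tb - mean(tb))^2))
    r <- num / den
    p <- NA_real_
  } else {
    ct <- stats::cor.test(a, b)
    r <- unname(ct$estimate)
    p <- ct$p.value
  }
  list(r = r, n = n, p = p, peaks = data.frame(cell = cells, fam = a, nov = b))
}

#' Observed versus expected PCC overlap across environments
#'
#' Under independent field allocation, the expected proportion of cells with
#' fields in both environments is the product of the two per-environment PCC
#' proportions. Reports per-session observed/expected proportions and their
#' differences, plus a one-sample t-test of the differences against zero
#' when several sessions are supplied.
#'
#' @param pcc_fam,pcc_nov a `PccResult` each, or lists of them (paired
#'   sessions).
#' @return An `OverlapStats` list: `sessions` (data.frame: p_fam, p_nov,
#'   p_both_observed, p_both_expected, difference), `mean_difference`,
#'   `t`, `p` (NA with fewer than 2 sessions).
#' @export
overlap_vs_expected <- function(pcc_fam, pcc_nov) {
  if (inherits(pcc_fam, "PccResult")) pcc_fam <- list(pcc_fam)
  if (inherits(pcc_nov, "PccResult")) pcc_nov <- list(pcc_nov)
  stopifnot(length(pcc_fam) == length(pcc_nov))
  rows <- list()
  for (i in seq_along(pcc_fam)) {
    f <- pcc_fam[[i]]$table$is_pcc
    n <- pcc_nov[[i]]$table$is_pcc
    stopifnot(length(f) == length(n))
    if (!length(f)) next
    p_f <- mean(f); p_n <- mean(n)
    obs <- mean(f & n)
    rows[[length(rows) + 1L]] <- data.frame(
      session = i, p_fam = p_f, p_nov = p_n,
      p_both_observed = obs, p_both_expected = p_f * p_n,
      difference = obs - p_f * p_n)
  }
  sessions <- do.call(rbind, rows)
  tt <- if (nrow(sessions) >= 2L && stats::sd(sessions$difference) > 0)
    stats::t.test(sessions$difference) else NULL
  structure(list(
    sessions = sessions,
    mean_difference = mean(sessions$difference),
    t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
    p = if (is.null(tt)) NA_real_ else tt$p.value
  ), class = "OverlapStats")
}

# z-score the whole laps x bins matrix of one cell over all finite entries
zscore_cell <- function(mat) {
  mu <- mean(mat, na.rm = TRUE)
  sdv <- stats::sd(as.numeric(mat), na.rm = TRUE)
  if (!is.finite(sdv) || sdv == 0) return(mat * NA_real_)
  (mat - mu) / sdv
}

#' Across-lap variability of peak activity (rate-remapping statistic)
#'
#' Each spatially tuned cell's laps x bins activity is z-scored over the
#' whole session, each lap's trace is convolved with a 5-bin Hanning window,
#' and the lap peak (location free) is extracted. Cells are assigned to zone
#' A or B by the bin of their across-lap peak. Within each configuration
#' epoch the SD of lap peaks is computed per cell (cells with fewer than 3
#' active laps in an epoch are excluded from it), then averaged per
#' zone x epoch. Elevated zone-B SD in a destabilized epoch is the
#' rate-remapping signature.
#'
#' @param binned a `BinnedActivity` spanning all epochs.
#' @param pcc a `PccResult` for the same tensor (only `is_pcc` cells enter).
#' @param epochs character/factor vector, one configuration label per lap.
#' @param zones list with `zone_a`, `zone_b` bin vectors.
#' @param fields optional field list enabling the in-field-mean variant
#'   restricted to fields whose across-epoch peak moved < 25 cm.
#' @return A `RateVariability` list: `per_cell` (cell, zone, epoch,
#'   sd_lap_peak, n_laps), `summary` (zone x epoch mean SDs),
#'   `per_cell_infield` (optional stable-field variant).
#' @export
lap_peak_variability <- function(binned, pcc, epochs, zones, fields = NULL) {
  stopifnot(length(epochs) == binned$n_laps)
  n_bins <- dim(binned$rate)[2]
  cells <- pcc$table$cell[pcc$table$is_pcc]
  per_cell <- list()
  for (cellk in cells) {
    z <- zscore_cell(binned$rate[, , cellk])
    if (binned$n_laps == 1L) z <- matrix(z, nrow = 1L)
    sm <- t(apply(z, 1, hann_smooth_circular, width = 5L))
    lap_peak <- apply(sm, 1, function(r)
      if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
    overall <- colMeans(sm, na.rm = TRUE)
    pk_bin <- which.max(ifelse(is.nan(overall), -Inf, overall))
    zone <- if (pk_bin %in% zones$zone_a) "A"
    else if (pk_bin %in% zones$zone_b) "B" else NA_character_
    raw <- binned$rate[, , cellk]
    if (binned$n_laps == 1L) raw <- matrix(raw, nrow = 1L)
    active <- rowSums(raw > 0, na.rm = TRUE) > 0
    for (ep in unique(epochs)) {
      laps <- which(epochs == ep & active & !is.na(lap_peak))
      if (length(laps) < 3L) next
      per_cell[[length(per_cell) + 1L]] <- data.frame(
        cell = cellk, zone = zone, epoch = ep,
        sd_lap_peak = stats::sd(lap_peak[laps]), n_laps = length(laps))
    }
  }
  per_cell <- if (length(per_cell)) do.call(rbind, per_cell) else
    data.frame(cell = integer(), zone = character(), epoch = character(),
               sd_lap_peak = numeric(), n_laps = integer())
  summary <- if (nrow(per_cell))
    stats::aggregate(sd_lap_peak ~ zone + epoch, per_cell, mean) else
      data.frame(zone = character(), epoch = character(), sd_lap_peak = numeric())
  out <- list(per_cell = per_cell, summary = summary)
  if (!is.null(fields))
    out$per_cell_infield <- infield_mean_variability(binned, fields, epochs)
  structure(out, class = "RateVariability")
}

# supplementary variant: SD of per-lap mean in-field z-scored activity, for
# fields whose mean peak location moved < 25 cm between the two epochs
infield_mean_variability <- function(binned, fields, epochs, stable_cm = 25) {
  n_bins <- dim(binned$rate)[2]
  eps <- unique(epochs)
  rows <- list()
  for (fi in seq_along(fields)) {
    f <- fields[[fi]]
    span <- circ_span_bins(f$start, f$end, n_bins)
    z <- zscore_cell(binned$rate[, , f$cell])
    if (binned$n_laps == 1L) z <- matrix(z, nrow = 1L)
    if (length(eps) == 2L) {
      pk_of <- function(ep) {
        tr <- colMeans(binned$rate[which(epochs == ep), , f$cell, drop = FALSE][, , 1,
                                                                               drop = FALSE],
                       na.rm = TRUE)
        which.max(ifelse(is.nan(tr), -Inf, tr))
      }
      moved <- circ_dist_bins(pk_of(eps[1]), pk_of(eps[2]), n_bins) * binned$bin_size
      if (!is.finite(moved) || moved >= stable_cm) next
    }
    infield <- rowMeans(z[, span, drop = FALSE], na.rm = TRUE)
    for (ep in eps) {
      laps <- which(epochs == ep & is.finite(infield))
      if (length(laps) < 3L) next
      rows[[length(rows) + 1L]] <- data.frame(
        field = fi, cell = f$cell, epoch = ep,
        sd_infield_mean = stats::sd(infield[laps]), n_laps = length(laps))
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(field = integer(), cell = integer(), epoch = character(),
               sd_infield_mean = numeric(), n_laps = integer())
}

#' Across-lap variability of running speed at each cell's lap peak
#'
#' Speed control for [lap_peak_variability()]: for each cell and lap, the
#' lap's occupancy-normalized mean speed in the bin where that lap's
#' (smoothed, z-scored) activity peaked; the SD of these speeds per epoch is
#' aggregated exactly like the activity variant. A flat zone x epoch profile
#' here rules out running speed as the source of rate variability.
#'
#' @inheritParams lap_peak_variability
#' @param rec the `SessionRecording` (for velocity).
#' @param env the `EnvironmentSpec` matching `binned`.
#' @param cfg a [preprocess_config()].
#' @return Same shape as [lap_peak_variability()]: `per_cell` with
#'   `sd_speed_at_peak`, `summary` with zone x epoch means.
#' @export
speed_at_peak_variability <- function(rec, env, binned, pcc, epochs, zones,
                                      cfg = preprocess_config()) {
  stopifnot(length(epochs) == binned$n_laps)
  vel <- bin_signal(rec, env, rec$velocity, cfg)
  stopifnot(nrow(vel) == binned$n_laps)
  cells <- pcc$table$cell[pcc$table$is_pcc]
  per_cell <- list()
  for (cellk in cells) {
    z <- zscore_cell(binned$rate[, , cellk])
    if (binned$n_laps == 1L) z <- matrix(z, nrow = 1L)
    sm <- t(apply(z, 1, hann_smooth_circular, width = 5L))
    pk_bins <- apply(sm, 1, function(r)
      if (all(is.na(r))) NA_integer_ else which.max(ifelse(is.na(r), -Inf, r)))
    overall <- colMeans(sm, na.rm = TRUE)
    zone_bin <- which.max(ifelse(is.nan(overall), -Inf, overall))
    zone <- if (zone_bin %in% zones$zone_a) "A"
    else if (zone_bin %in% zones$zone_b) "B" else NA_character_
    speeds <- vel[cbind(seq_len(binned$n_laps), pk_bins)]
    for (ep in unique(epochs)) {
      laps <- which(epochs == ep & is.finite(speeds))
      if (length(laps) < 3L) next
      per_cell[[length(per_cell) + 1L]] <- data.frame(
        cell = cellk, zone = zone, epoch = ep,
        sd_speed_at_peak = stats::sd(speeds[laps]), n_laps = length(laps))
    }
  }
  per_cell <- if (length(per_cell)) do.call(rbind, per_cell) else
    data.frame(cell = integer(), zone = character(), epoch = character(),
               sd_speed_at_peak = numeric(), n_laps = integer())
  summary <- if (nrow(per_cell))
    stats::aggregate(sd_speed_at_peak ~ zone + epoch, per_cell, mean) else
      data.frame(zone = character(), epoch = character(),
                 sd_speed_at_peak = numeric())
  structure(list(per_cell = per_cell, summary = summary),
            class = "RateVariability")
}
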