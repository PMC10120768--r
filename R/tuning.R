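# Position tuning: three-step place-field criterion, spatial information
# with circular-shift shuffles, sparsity, and split-half peak ordering.

#' Tuning configuration
#'
#' @param peak_factor candidate peaks must exceed `peak_factor` times the
#'   median of the smoothed lap-averaged trace (default 3.5).
#' @param trough_frac boundary rule (b): the nearest trough after which the
#'   trace drops below this fraction of the peak (default 0.7).
#' @param reliability_frac fraction of laps on which the in-field per-lap
#'   peak must beat 3.5x baseline; the requirement is
#'   `max(ceiling(reliability_frac * M), 5)` laps (default 1/3).
#' @param min_active_laps floor of the lap requirement (default 5).
#' @param min_size_cm,max_size_cm field size bounds in cm (defaults 20, 150).
#' @param hann_bins smoothing window for the lap-averaged trace (default 5).
#' @param smooth_percentiles compute the step-1 median on the smoothed
#'   (default) or raw lap-average trace.
#' @return A list of class `TuningConfig`.
#' @export
tuning_config <- function(peak_factor = 3.5, trough_frac = 0.7,
                          reliability_frac = 1 / 3, min_active_laps = 5L,
                          min_size_cm = 20, max_size_cm = 150,
                          hann_bins = 5L, smooth_percentiles = TRUE) {
  structure(list(peak_factor = peak_factor, trough_frac = trough_frac,
                 reliability_frac = reliability_frac,
                 min_active_laps = as.integer(min_active_laps),
                 min_size_cm = min_size_cm, max_size_cm = max_size_cm,
                 hann_bins = as.integer(hann_bins),
                 smooth_percentiles = smooth_percentiles),
            class = "TuningConfig")
}

# circular local maxima: strictly greater than the left neighbor and at
# least the right neighbor, so plateaus take their leftmost bin (ties are
# measure-zero on smoothed traces anyway).
local_maxima_circular <- function(x) {
  n <- length(x)
  left <- x[c(n, seq_len(n - 1L))]
  right <- x[c(seq_len(n - 1L) + 1L, 1L)]
  which(x > left & x >= right)
}

# walk outward from `peak` in direction `dirn` (+1/-1) on the (raw) trace;
# the boundary is the last in-field bin on that side: the walk stops at the
# first bin below `med` (rule a) or at the closest trough after which the
# trace falls below trough_frac * peak (rule b), whichever comes first; the
# stopping bin itself (crossing or trough) belongs to neither field.
grow_boundary <- function(trace, peak, dirn, med, trough_frac, n_bins,
                          peakval = trace[peak]) {
  trough_bound <- NA_integer_   # bin before the most recent trough
  prev <- peakval
  limit <- n_bins %/% 2L
  bound <- (peak + dirn * limit - 1L) %% n_bins + 1L
  prev_bin <- peak
  for (s in seq_len(limit)) {
    i <- (peak + dirn * s - 1L) %% n_bins + 1L
    nxt <- (peak + dirn * (s + 1L) - 1L) %% n_bins + 1L
    if (is.na(trace[i])) { bound <- prev_bin; break }
    if (trace[i] < med) { bound <- prev_bin; break }
    if (is.na(trough_bound) && trace[i] <= prev &&
        (is.na(trace[nxt]) || trace[i] <= trace[nxt]))
      trough_bound <- prev_bin   # first (closest) trough wins
    if (trace[i] < trough_frac * peakval && !is.na(trough_bound)) {
      bound <- trough_bound
      break
    }
    prev <- trace[i]
    prev_bin <- i
  }
  bound
}

#' Detect place fields of one cell (three-step criterion)
#'
#' Step 1: the lap-averaged rate trace is circularly smoothed with a 5-bin
#' Hanning window; local maxima of the smoothed trace exceeding 3.5 times
#' its 50th percentile are candidate fields. Each candidate's boundary then
#' grows along the raw lap-average (the smoothing only serves peak finding)
#' in both circular directions to the nearer of (a) the first bin below the
#' trace median or (b) the closest trough after which the trace falls below
#' 70% of the peak; the stopping bin itself lies outside the field. Step 2: with baseline = (50th - 5th percentile of the
#' cell's activity over all bins and laps), a field is kept only if its
#' per-lap in-field peak exceeds 3.5x baseline on at least
#' `max(ceiling(reliability_frac * M), 5)` laps. Step 3: fields smaller than
#' 20 cm or larger than 150 cm are eliminated. Overlapping candidates are
#' merged, keeping the higher peak.
#'
#' @param binned a `BinnedActivity` (dF/F channel by convention).
#' @param cell cell index.
#' @param cfg a [tuning_config()].
#' @return List of `PlaceField` lists (`cell`, `environment`, `peak_bin`,
#'   `start`, `end` circular boundary bins, `size_cm`, `active_laps`,
#'   `onset_lap`, `peak_rate`); empty for all-zero cells or fewer than 5
#'   laps.
#' @export
detect_fields <- function(binned, cell, cfg = tuning_config()) {
  m <- binned$n_laps
  if (m < 5L) {
    message("detect_fields: fewer than 5 laps; skipping")
    return(list())
  }
  n_bins <- dim(binned$rate)[2]
  rates <- binned$rate[, , cell, drop = FALSE][, , 1]
  lapavg <- colMeans(rates, na.rm = TRUE)
  lapavg[is.nan(lapavg)] <- NA_real_
  if (all(is.na(lapavg)) || all(lapavg == 0, na.rm = TRUE)) return(list())
  trace <- hann_smooth_circular(lapavg, cfg$hann_bins)
  med_src <- if (cfg$smooth_percentiles) trace else lapavg
  med <- stats::median(med_src, na.rm = TRUE)
  cand <- local_maxima_circular(ifelse(is.na(trace), -Inf, trace))
  cand <- cand[trace[cand] > cfg$peak_factor * med]
  if (!length(cand)) return(list())
  fields <- lapply(cand, function(pk) {
    start <- grow_boundary(lapavg, pk, -1L, med, cfg$trough_frac, n_bins,
                           peakval = trace[pk])
    end <- grow_boundary(lapavg, pk, +1L, med, cfg$trough_frac, n_bins,
                         peakval = trace[pk])
    span <- circ_span_bins(start, end, n_bins)
    list(cell = cell, environment = binned$env, peak_bin = pk,
         start = start, end = end,
         size_cm = length(span) * binned$bin_size,
         peak_rate = trace[pk], span = span)
  })
  # merge overlapping candidates, keeping the higher peak
  keep <- rep(TRUE, length(fields))
  ord <- order(vapply(fields, `[[`, numeric(1), "peak_rate"), decreasing = TRUE)
  claimed <- logical(n_bins)
  for (i in ord) {
    sp <- fields[[i]]$span
    if (any(claimed[sp])) keep[i] <- FALSE else claimed[sp] <- TRUE
  }
  fields <- fields[keep]
  # Step 2: lap reliability against session baseline
  q <- stats::quantile(rates, c(0.05, 0.5), na.rm = TRUE, names = FALSE)
  baseline <- q[2] - q[1]
  need <- max(ceiling(cfg$reliability_frac * m), cfg$min_active_laps)
  fields <- Filter(Negate(is.null), lapply(fields, function(f) {
    infield <- rates[, f$span, drop = FALSE]
    lap_peak <- apply(infield, 1, function(r)
      if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
    active <- which(!is.na(lap_peak) & lap_peak > cfg$peak_factor * baseline)
    if (length(active) < need) return(NULL)
    f$active_laps <- active
    f$onset_lap <- min(active)
    f
  }))
  # Step 3: size bounds
  Filter(function(f) f$size_cm >= cfg$min_size_cm && f$size_cm <= cfg$max_size_cm,
         fields)
}

#' Classify position-correlated cells (PCCs) for one environment
#'
#' Runs [detect_fields()] on every cell; a cell is a PCC iff it has at least
#' one retained place field. Spatial information (with its 100-shuffle null)
#' and sparsity are computed from the event channel when a separate
#' `si_binned` tensor is supplied (the convention: dF/F for field detection,
#' deconvolved events for SI), otherwise from `binned` itself.
#'
#' @param binned `BinnedActivity` used for field detection (dF/F).
#' @param si_binned optional `BinnedActivity` for SI/sparsity (deconv).
#' @param cfg a [tuning_config()].
#' @param n_shuffles shuffles for the SI null (default 100).
#' @param seed RNG seed for the shuffles.
#' @param zones optional list with `zone_a`, `zone_b` bin vectors; when
#'   given, each field's peak is assigned a zone.
#' @return A `PccResult` list: `table` (tidy per-cell data.frame with
#'   `cell`, `is_pcc`, `n_fields`, `peak_bin`, `size_cm`, `si`,
#'   `si_shuffle_p`, `sparsity`, `zone`), `fields` (flat list of fields),
#'   `pcc_fraction`, and `si_shuffle` (cells x n_shuffles matrix).
#' @export
classify_pcc <- function(binned, si_binned = NULL, cfg = tuning_config(),
                         n_shuffles = 100L, seed = NULL, zones = NULL) {
  if (is.null(si_binned)) si_binned <- binned
  ncell <- dim(binned$rate)[3]
  if (!is.null(seed)) set.seed(seed)
  fields_all <- list()
  rows <- vector("list", ncell)
  shuf_mat <- matrix(NA_real_, ncell, n_shuffles)
  for (cellk in seq_len(ncell)) {
    fl <- detect_fields(binned, cellk, cfg)
    fields_all <- c(fields_all, fl)
    si <- spatial_information(si_binned, cellk, n_shuffles = n_shuffles)
    shuf_mat[cellk, ] <- si$shuffle
    peak <- if (length(fl)) fl[[which.max(vapply(fl, `[[`, numeric(1), "peak_rate"))]]$peak_bin else NA_integer_
    zone <- NA_character_
    if (!is.null(zones) && !is.na(peak)) {
      if (peak %in% zones$zone_a) zone <- "A"
      else if (peak %in% zones$zone_b) zone <- "B"
    }
    rows[[cellk]] <- data.frame(
      cell = cellk, is_pcc = length(fl) > 0L, n_fields = length(fl),
      peak_bin = peak,
      size_cm = if (length(fl)) fl[[1]]$size_cm else NA_real_,
      si = si$si,
      si_shuffle_p = mean(si$shuffle >= si$si),
      sparsity = sparsity(si_binned, cellk),
      zone = zone, stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, rows)
  structure(list(table = tab, fields = fields_all,
                 pcc_fraction = mean(tab$is_pcc), si_shuffle = shuf_mat,
                 env = binned$env),
            class = "PccResult")
}

#' Spatial information of one cell (bits per second)
#'
#' `SI = sum_i p_i * f_i * log2(f_i / fbar)` where `p_i` is the occupancy
#' probability of bin i, `f_i` the lap-averaged rate in bin i and
#' `fbar = sum_i p_i f_i`; bins with zero rate contribute zero. The null
#' distribution circularly shifts each lap's binned activity by an
#' independent random integer (1..n_bins-1) and recomputes, `n_shuffles`
#' times. Requires a nonnegative signal; use the deconvolved channel.
#'
#' @param binned a `BinnedActivity` (event channel).
#' @param cell cell index.
#' @param n_shuffles number of circular-shift shuffles (default 100).
#' @param seed optional RNG seed.
#' @return List with `si` (bits/s), `shuffle` (length `n_shuffles`), and
#'   `flag` ("zero_rate" when the mean rate is 0, in which case SI = 0).
#' @export
spatial_information <- function(binned, cell, n_shuffles = 100L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_bins <- dim(binned$rate)[2]
  rates <- binned$rate[, , cell, drop = FALSE][, , 1]
  if (binned$n_laps == 1L) rates <- matrix(rates, nrow = 1L)
  p <- binned$p_i
  si_of <- function(r) {
    f_i <- colMeans(r, na.rm = TRUE)
    f_i[is.nan(f_i)] <- 0
    fbar <- sum(p * f_i)
    if (fbar <= 0) return(0)
    pos <- f_i > 0
    sum(p[pos] * f_i[pos] * log2(f_i[pos] / fbar))
  }
  si <- si_of(rates)
  shuffle <- vapply(seq_len(n_shuffles), function(s) {
    shifts <- sample.int(n_bins - 1L, nrow(rates), replace = TRUE)
    shifted <- rates
    for (l in seq_len(nrow(rates)))
      shifted[l, ] <- rates[l, (seq_len(n_bins) - 1L - shifts[l]) %% n_bins + 1L]
    si_of(shifted)
  }, numeric(1))
  flag <- if (sum(p * colMeans(rates, na.rm = TRUE), na.rm = TRUE) <= 0)
    "zero_rate" else NA_character_
  list(si = si, shuffle = shuffle, flag = flag)
}

#' Lifetime sparsity of one cell
#'
#' `(sum_i p_i f_i)^2 / sum_i p_i f_i^2`; 1 for uniform activity, `1/N` for
#' activity confined to one of N equal-occupancy bins, NA for silent cells.
#'
#' @inheritParams spatial_information
#' @return Scalar in `(0, 1]`, or NA for an all-zero cell.
#' @export
sparsity <- function(binned, cell) {
  rates <- binned$rate[, , cell, drop = FALSE][, , 1]
  if (binned$n_laps == 1L) rates <- matrix(rates, nrow = 1L)
  f_i <- colMeans(rates, na.rm = TRUE)
  f_i[is.nan(f_i)] <- 0
  p <- binned$p_i
  denom <- sum(p * f_i^2)
  if (denom <= 0) return(NA_real_)
  sum(p * f_i)^2 / denom
}

#' Split-half peak ordering for population sequence plots
#'
#' Peak bins are computed on a random 5-lap subset of the final 10 laps; the
#' returned matrix averages the complementary laps, so an apparent sequence
#' cannot be an artifact of sorting noise. With fewer than 10 laps the split
#' falls back to odd (ordering) versus even (averaging) laps.
#'
#' @param binned a `BinnedActivity`.
#' @param seed RNG seed for the lap subset.
#' @return List: `order` (cell indices sorted by ascending peak bin),
#'   `peak_bin` (per cell), `matrix` (cells x bins held-out lap average,
#'   rows in original cell order).
#' @export
order_by_peak <- function(binned, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- binned$n_laps
  if (m >= 10L) {
    final10 <- (m - 9L):m
    peak_laps <- sort(sample(final10, 5L))
    plot_laps <- setdiff(seq_len(m), peak_laps)
  } else {
    message("order_by_peak: fewer than 10 laps; using odd/even lap split")
    peak_laps <- seq(1L, m, by = 2L)
    plot_laps <- setdiff(seq_len(m), peak_laps)
    if (!length(plot_laps)) plot_laps <- peak_laps
  }
  avg_over <- function(laps) {
    a <- apply(binned$rate[laps, , , drop = FALSE], c(2, 3), mean, na.rm = TRUE)
    a[is.nan(a)] <- 0
    a
  }
  pk_mat <- avg_over(peak_laps)           # bins x cells
  peak_bin <- apply(pk_mat, 2, which.max)
  held <- t(avg_over(plot_laps))          # cells x bins
  list(order = order(peak_bin), peak_bin = peak_bin, matrix = held,
       peak_laps = peak_laps, plot_laps = plot_laps)
}
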