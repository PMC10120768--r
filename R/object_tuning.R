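# Object-versus-position tuning: activity aligned to objects, potential
# slots, or random locations, with a shuffle-based double criterion.

#' Object-tuning z cutoff
#'
#' The one-sided standard-normal 99% quantile used by criterion (2);
#' `qnorm(0.99) = 2.3263` to four decimals.
#' @return Numeric scalar.
#' @export
object_tuning_z_cutoff <- function() stats::qnorm(0.99)

#' Object-tuning configuration
#'
#' @param n_shuffles random-alignment draws for the null (default 1000).
#' @param window_before_bins,window_after_bins alignment window geometry: 3
#'   bins (9 cm at 3.77 cm bins) before to 1 bin (3 cm) after the landmark,
#'   i.e. a 4-bin window ending one bin after the landmark's bin.
#' @param z_cutoff criterion-(2) z threshold (default
#'   [object_tuning_z_cutoff()], p = 0.01 one-sided).
#' @param null_quantile criterion-(1) per-bin null percentile (default
#'   0.975).
#' @return A list of class `ObjectTuningConfig`.
#' @export
object_tuning_config <- function(n_shuffles = 1000L, window_before_bins = 3L,
                                 window_after_bins = 1L,
                                 z_cutoff = object_tuning_z_cutoff(),
                                 null_quantile = 0.975) {
  structure(list(n_shuffles = as.integer(n_shuffles),
                 window_before_bins = as.integer(window_before_bins),
                 window_after_bins = as.integer(window_after_bins),
                 z_cutoff = z_cutoff, null_quantile = null_quantile),
            class = "ObjectTuningConfig")
}

# window bins for a landmark bin b: 4 consecutive bins ending 1 bin after b
window_bins_for <- function(b, cfg, n_bins) {
  len <- cfg$window_before_bins + cfg$window_after_bins
  (b + cfg$window_after_bins - seq_len(len)) %% n_bins + 1L
}

#' Align one cell's binned activity to per-lap landmark positions
#'
#' Extracts, for every lap, the 4-bin window ending one bin after the
#' landmark's bin (covering roughly 9 cm before to 3 cm after it) and
#' stacks the laps. Landmarks may move between laps (shifting objects);
#' landmarks inside the tunnel are rejected since objects never occupy it.
#'
#' @param binned a `BinnedActivity`.
#' @param cell cell index.
#' @param landmark_bins integer vector: the landmark's bin on each lap
#'   (length 1 recycles to all laps).
#' @param cfg an [object_tuning_config()].
#' @param tunnel_bins bins the landmark must avoid (optional check).
#' @return An `AlignmentWindow`: laps x window-bins matrix (window bin 1 is
#'   farthest before the landmark).
#' @export
align_activity <- function(binned, cell, landmark_bins,
                           cfg = object_tuning_config(),
                           tunnel_bins = integer()) {
  n_bins <- dim(binned$rate)[2]
  m <- binned$n_laps
  if (length(landmark_bins) == 1L) landmark_bins <- rep(landmark_bins, m)
  stopifnot(length(landmark_bins) == m)
  if (length(tunnel_bins) && any(landmark_bins %in% tunnel_bins))
    stop("align_activity: landmark inside tunnel bins")
  len <- cfg$window_before_bins + cfg$window_after_bins
  out <- matrix(NA_real_, m, len)
  for (l in seq_len(m)) {
    wb <- rev(window_bins_for(landmark_bins[l], cfg, n_bins))
    out[l, ] <- binned$rate[l, wb, cell]
  }
  structure(out, class = c("AlignmentWindow", class(out)))
}

#' Null distribution of aligned-window statistics for one cell
#'
#' Each of `n_shuffles` draws aligns every lap to an independently random
#' permitted location (uniform over the six zone-B slots) and records the
#' per-window-bin lap-averages and the window-averaged mean, mirroring the
#' statistics used for the real alignments.
#'
#' @param binned a `BinnedActivity`.
#' @param cell cell index.
#' @param slot_bins bins of the six permitted slot locations.
#' @param cfg an [object_tuning_config()].
#' @param seed optional RNG seed.
#' @return List: `bin_means` (n_shuffles x window-bins), `win_means`
#'   (n_shuffles).
#' @export
shuffle_null <- function(binned, cell, slot_bins,
                         cfg = object_tuning_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_bins <- dim(binned$rate)[2]
  m <- binned$n_laps
  len <- cfg$window_before_bins + cfg$window_after_bins
  # per-lap aligned windows for each slot, computed once: m x len x n_slot
  slot_win <- array(NA_real_, c(m, len, length(slot_bins)))
  for (s in seq_along(slot_bins)) {
    wb <- rev(window_bins_for(slot_bins[s], cfg, n_bins))
    slot_win[, , s] <- binned$rate[, wb, cell]
  }
  draws <- matrix(sample.int(length(slot_bins), m * cfg$n_shuffles,
                             replace = TRUE), m, cfg$n_shuffles)
  bin_means <- matrix(NA_real_, cfg$n_shuffles, len)
  win_means <- numeric(cfg$n_shuffles)
  lap_idx <- seq_len(m)
  for (d in seq_len(cfg$n_shuffles)) {
    picked <- matrix(NA_real_, m, len)
    sidx <- draws[, d]
    for (j in seq_len(len))
      picked[, j] <- slot_win[cbind(lap_idx, j, sidx)]
    bin_means[d, ] <- colMeans(picked, na.rm = TRUE)
    win_means[d] <- mean(picked, na.rm = TRUE)
  }
  list(bin_means = bin_means, win_means = win_means)
}

# double criterion for one aligned stack against one null
eval_criteria <- function(aligned, null, cfg) {
  m_eff <- colSums(!is.na(aligned))
  mu <- colMeans(aligned, na.rm = TRUE)
  sem <- apply(aligned, 2, stats::sd, na.rm = TRUE) / sqrt(pmax(m_eff, 1))
  qs <- apply(null$bin_means, 2, stats::quantile, probs = cfg$null_quantile,
              na.rm = TRUE, names = FALSE)
  crit1 <- any(mu - sem > qs, na.rm = TRUE)
  nm <- mean(null$win_means, na.rm = TRUE)
  nsd <- stats::sd(null$win_means, na.rm = TRUE)
  if (!is.finite(nsd) || nsd == 0)
    return(list(crit1 = crit1, crit2 = NA, z = NA_real_, unclassifiable = TRUE))
  z <- (mean(aligned, na.rm = TRUE) - nm) / nsd
  list(crit1 = crit1, crit2 = z > cfg$z_cutoff, z = z, unclassifiable = FALSE)
}

#' Classify cells as position-, object-, both-, or neither-tuned
#'
#' For every cell, activity is aligned to (i) each of the six potential slot
#' locations and (ii) the per-lap actual position of each of the four zone-B
#' objects; one 1000-draw random-alignment null per cell provides the
#' reference. A cell is tuned at a landmark iff both: (1) at some window bin
#' the lap-mean minus SEM exceeds the null's 97.5th percentile of lap-means
#' at that bin, and (2) the lap-and-bin-averaged window activity has a
#' z-score above 2.3263 against the null's window averages. Any passing
#' slot makes the cell position-tuned; any passing object makes it
#' object-tuned.
#'
#' @param binned a `BinnedActivity` for the object-task environment.
#' @param env an `EnvironmentSpec` with `object_slots` and (for the object
#'   frame) `lap_object_table` rows matching `binned$lap_ids`.
#' @param cfg an [object_tuning_config()].
#' @param seed RNG seed (one generator for the whole call).
#' @param cells cell subset (default all).
#' @return A `TuningClassification` list: `table` (cell, category,
#'   tuned_position, tuned_object, plus per-slot/per-object z-scores and
#'   flags), `slot_pass`, `slot_pass_z` (cells x 6 logical: double and
#'   z-only criteria), `object_pass` (cells x 4).
#' @export
classify_tuning <- function(binned, env, cfg = object_tuning_config(),
                            seed = NULL, cells = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(!is.null(env$object_slots))
  n_bins <- dim(binned$rate)[2]
  slot_bins <- position_to_bin(env$object_slots, env$track_length, env$n_bins)
  if (is.null(cells)) cells <- seq_len(dim(binned$rate)[3])
  tab <- env$lap_object_table
  has_objects <- !is.null(tab)
  if (has_objects) {
    stopifnot(nrow(tab) >= max(binned$lap_ids))
    tab <- tab[binned$lap_ids, , drop = FALSE]
  }
  n_obj <- if (has_objects) ncol(tab) else 0L
  slot_pass <- matrix(NA, length(cells), length(slot_bins))
  slot_pass_z <- matrix(NA, length(cells), length(slot_bins))
  slot_z <- matrix(NA_real_, length(cells), length(slot_bins))
  obj_pass <- matrix(NA, length(cells), max(n_obj, 1L))
  rows <- vector("list", length(cells))
  for (ci in seq_along(cells)) {
    cellk <- cells[ci]
    null <- shuffle_null(binned, cellk, slot_bins, cfg)
    unclass_flag <- FALSE
    for (s in seq_along(slot_bins)) {
      al <- align_activity(binned, cellk, slot_bins[s], cfg)
      ev <- eval_criteria(al, null, cfg)
      unclass_flag <- unclass_flag || ev$unclassifiable
      slot_pass[ci, s] <- isTRUE(ev$crit1) && isTRUE(ev$crit2)
      slot_pass_z[ci, s] <- isTRUE(ev$crit2)
      slot_z[ci, s] <- ev$z
    }
    if (has_objects) {
      for (o in seq_len(n_obj)) {
        al <- align_activity(binned, cellk, slot_bins[tab[, o]], cfg)
        ev <- eval_criteria(al, null, cfg)
        obj_pass[ci, o] <- isTRUE(ev$crit1) && isTRUE(ev$crit2)
      }
    }
    tuned_pos <- any(slot_pass[ci, ], na.rm = TRUE)
    tuned_obj <- has_objects && any(obj_pass[ci, ], na.rm = TRUE)
    category <- if (unclass_flag) "unclassifiable"
    else if (tuned_pos && tuned_obj) "both"
    else if (tuned_pos) "position"
    else if (tuned_obj) "object" else "neither"
    rows[[ci]] <- data.frame(cell = cellk, category = category,
                             tuned_position = tuned_pos,
                             tuned_object = tuned_obj,
                             max_slot_z = suppressWarnings(max(slot_z[ci, ],
                                                               na.rm = TRUE)))
  }
  structure(list(table = do.call(rbind, rows), slot_pass = slot_pass,
                 slot_pass_z = slot_pass_z, slot_z = slot_z,
                 object_pass = if (has_objects) obj_pass else NULL,
                 n_shuffles = cfg$n_shuffles),
            class = "TuningClassification")
}
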