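# Lick behavior: precision of anticipatory licking at hidden reward sites.

#' Anticipatory and post-reward bin sets for a reward map
#'
#' The 5 bins before each reward bin are anticipatory; the reward bin itself
#' plus the 4 following bins are post-reward (so 2 rewards exclude 10 bins
#' and 90 remain scored, giving the 1/9 chance level). Windows wrap
#' circularly across the lap seam.
#' @keywords internal
lick_windows <- function(reward_bins, n_bins) {
  n_bins <- as.integer(n_bins)
  ant <- unique(as.integer(vapply(reward_bins, function(r)
    as.integer((r - 5:1 - 1L) %% n_bins + 1L), integer(5))))
  post <- unique(as.integer(vapply(reward_bins, function(r)
    as.integer((r + 0:4 - 1L) %% n_bins + 1L), integer(5))))
  list(anticipatory = ant, post = post)
}

#' Core lick-precision computation on a lap x bin lick matrix
#'
#' `precision = anticipatory lick-bins / (total lick-bins - post-reward
#' lick-bins)`; a lick-bin is a (lap, bin) pair with at least one lick, so
#' bursts are not weighted more than single exploratory licks. Chance level
#' is 10/90 = 1/9 for two reward sites on a 100-bin track.
#'
#' @param lick_mat laps x n_bins logical/0-1 matrix.
#' @param reward_bins 1-based reward bin indices.
#' @return A `LickSummary` list: `precision`, `anticipatory_count`,
#'   `post_reward_count`, `nonspecific_count`, `total_count`,
#'   `chance_level` (1/9), `lick_bin_matrix`.
#' @export
lick_precision_matrix <- function(lick_mat, reward_bins) {
  n_bins <- ncol(lick_mat)
  lick_mat <- lick_mat > 0
  w <- lick_windows(reward_bins, n_bins)
  total <- sum(lick_mat)
  ant <- sum(lick_mat[, w$anticipatory, drop = FALSE])
  post <- sum(lick_mat[, w$post, drop = FALSE])
  denom <- total - post
  structure(list(
    precision = if (denom > 0) ant / denom else NA_real_,
    anticipatory_count = ant, post_reward_count = post,
    nonspecific_count = total - ant - post, total_count = total,
    chance_level = 10 / 90, lick_bin_matrix = lick_mat
  ), class = "LickSummary")
}

#' Lick precision for one environment of a session
#'
#' Maps each lick time to its (lap, bin), binarizes per bin, and scores
#' precision against the environment's reward map. An alternative reward
#' map (e.g. the familiar environment's former reward bins evaluated on
#' novel laps) can be scored alongside.
#'
#' @param rec a `SessionRecording`.
#' @param env an `EnvironmentSpec` with `reward_bins` of length 2.
#' @param alt_reward_bins optional alternative reward bins to score the same
#'   lick matrix against (returned as `$alternative`).
#' @return A `LickSummary` (see [lick_precision_matrix()]), with
#'   `$alternative` when requested.
#' @export
lick_precision <- function(rec, env, alt_reward_bins = NULL) {
  stopifnot(length(env$reward_bins) >= 1L)
  in_env <- which(rec$env == env$name)
  lap_ids <- sort(unique(rec$lap[in_env]))
  si <- findInterval(rec$lick_times, rec$time)
  si <- si[si >= 1L]
  si <- si[si %in% in_env]
  bins <- position_to_bin(rec$position[si], env$track_length, env$n_bins)
  laps <- match(rec$lap[si], lap_ids)
  mat <- matrix(0L, length(lap_ids), env$n_bins)
  ok <- !is.na(laps)
  if (any(ok)) mat[cbind(laps[ok], bins[ok])] <- 1L
  out <- lick_precision_matrix(mat, env$reward_bins)
  if (!is.null(alt_reward_bins))
    out$alternative <- lick_precision_matrix(mat, alt_reward_bins)
  out
}
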