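# Fixtures are built in code; no binary data ships with the package.

# BinnedActivity constructed directly from a rate tensor (uniform occupancy),
# for unit tests that do not need a full session.
binned_from_rate <- function(rate, track_length = 377, signal_kind = "dff",
                             occupancy = NULL) {
  m <- dim(rate)[1]; nb <- dim(rate)[2]
  occ <- if (is.null(occupancy)) matrix(1, m, nb) else occupancy
  tot <- colSums(occ)
  structure(list(rate = rate, occupancy = occ, p_i = tot / sum(tot),
                 bin_size = track_length / nb, signal_kind = signal_kind,
                 env = "env", track_length = track_length,
                 lap_ids = seq_len(m), n_laps = m, n_cells = dim(rate)[3]),
            class = "BinnedActivity")
}

# Hand-built session: constant-speed laps on a short track, fully
# deterministic, with caller-supplied cell signal matrices.
simple_session <- function(n_laps = 6, track_length = 100, speed = 5,
                           frame_rate = 5, dff = NULL, deconv = NULL,
                           n_cells = 2, env_name = "familiar",
                           reward_bins = c(25L, 75L), n_bins = 100L) {
  dt <- 1 / frame_rate
  per_lap <- ceiling(track_length / speed / dt)
  n <- per_lap * n_laps
  pos <- ((seq_len(n) - 1) * speed * dt) %% track_length
  lap <- rep(seq_len(n_laps), each = per_lap)[seq_len(n)]
  if (is.null(dff)) dff <- matrix(1, n_cells, n)
  spec <- environment_spec(env_name, track_length, n_bins = n_bins,
                           reward_bins = reward_bins,
                           tunnel_bins = c(1:2, (n_bins - 1):n_bins))
  session_recording(
    time = (seq_len(n) - 1) * dt, position = pos,
    velocity = rep(speed, n), lap = lap, env = rep(env_name, n),
    frame_rate_hz = frame_rate, dff = dff, deconv = deconv,
    envs = stats::setNames(list(spec), env_name)
  )
}

# Place-field rate tensor with planted fields for tuning tests.
# centers_bin: per-cell peak bin (NA = untuned flat cell). shape "gauss"
# takes width_bins as the Gaussian sigma; "cosine" plants a compact
# half-cosine bump whose support is ~width_bins bins. hash_amp adds a
# deterministic per-lap baseline hash (fast sinusoid with lap-varying
# phase), mimicking the nonzero activity floor of real dF/F that anchors
# the percentile-based thresholds.
planted_rate_tensor <- function(n_laps, n_bins, centers_bin, width_bins = 8,
                                amp = 2, base = 0.02, active_laps = NULL,
                                noise_sd = 0, shape = "gauss",
                                hash_amp = 0) {
  ncell <- length(centers_bin)
  rate <- array(base, c(n_laps, n_bins, ncell))
  if (hash_amp > 0) {
    for (l in seq_len(n_laps)) {
      hash <- hash_amp * (1 + sin(2 * pi * 37 * seq_len(n_bins) / n_bins +
                                    2 * pi * 0.37 * l)) / 2
      rate[l, , ] <- rate[l, , ] + hash
    }
  }
  for (k in seq_len(ncell)) {
    if (is.na(centers_bin[k])) next
    d <- vrplace:::circ_dist_bins(seq_len(n_bins), centers_bin[k], n_bins)
    prof <- if (shape == "gauss") amp * exp(-d^2 / (2 * width_bins^2)) else
      amp * ifelse(d < width_bins / 2, cospi(d / width_bins), 0)
    laps <- if (is.null(active_laps)) seq_len(n_laps) else active_laps[[k]]
    for (l in laps) rate[l, , k] <- rate[l, , k] + prof
  }
  if (noise_sd > 0)
    rate <- rate + array(abs(rnorm(length(rate), 0, noise_sd)), dim(rate))
  rate
}

# minimal PccResult for remapping statistics
fake_pcc <- function(is_pcc, peak_bin = NULL, n_fields = NULL) {
  n <- length(is_pcc)
  structure(list(table = data.frame(
    cell = seq_len(n), is_pcc = is_pcc,
    n_fields = if (is.null(n_fields)) as.integer(is_pcc) else n_fields,
    peak_bin = if (is.null(peak_bin)) ifelse(is_pcc, 50L, NA_integer_) else peak_bin
  )), class = "PccResult")
}

# cached small simulated sessions shared across test files
.sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(key, cfg) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- simulate_session(cfg)
  .sim_cache[[key]]
}
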