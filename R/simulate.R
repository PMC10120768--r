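# Synthetic VR sessions with planted ground truth. The generator emulates
# the recorded conditions: GCaMP6s-like slow transients sampled at 7 Hz,
# circular tracks of 314-503 cm in 100 bins, 10-20 laps per environment,
# familiar-to-novel teleportation at the tunnel midpoint, two hidden reward
# sites, and (for the object task) a 377 cm track with zones A/B and 4
# objects reshuffled over 6 zone-B slots per lap.

#' Scenario configuration for the synthetic-session generator
#'
#' Defaults state the experimental world: 7 Hz frames, ~15 cm/s running
#' with occasional sub-1 cm/s pauses, 314 cm familiar and 503 cm novel
#' tracks (377 cm for object scenarios), 12 familiar + 15 novel laps,
#' familiar/novel PCC fractions of 0.27/0.19 allocated independently,
#' ~35 cm Gaussian fields with in-field event rates around 1.5 ev/s,
#' novel-field onset within the first laps with a short rate ramp, a 1.5 s
#' single-exponential calcium kernel, and lick precisions of 0.40
#' (familiar) / 0.27 (novel).
#'
#' @param scenario `"teleportation"` (familiar then novel environment),
#'   `"fixed"`, `"shifting"`, or `"destabilized"` (fixed epoch then
#'   shifting epoch of the same object environment).
#' @param seed integer; fully determines every output.
#' @param n_cells number of cells.
#' @param ... overrides for any default listed in the function definition
#'   (track lengths, lap counts, field statistics, noise levels, jitter
#'   SDs, `com_drift_cm_per_lap`, `object_locked_frac`,
#'   `overlap_excess`, `precision_target_*`, ...).
#' @return A list of class `ScenarioConfig`.
#' @export
scenario_config <- function(scenario = c("teleportation", "fixed", "shifting",
                                         "destabilized"),
                            seed = 1L, n_cells = 150L, ...) {
  scenario <- match.arg(scenario)
  cfg <- list(
    scenario = scenario, seed = as.integer(seed), n_cells = as.integer(n_cells),
    frame_rate_hz = 7,
    track_length_fam = 314, track_length_nov = 503, track_length_obj = 377,
    n_laps_fam = 12L, n_laps_nov = 15L,
    n_laps = 15L, n_laps_pre = 12L, n_laps_destab = 15L,
    mean_speed = 15, speed_sd = 4, speed_theta = 0.8,
    pause_hazard = 0.01, pause_mean_s = 3, pause_speed = 0.3,
    p_field_fam = 0.27, p_field_nov = 0.19, overlap_excess = 0,
    p_field = 0.25, object_locked_frac = 0,
    width_mean = 35, width_sd = 8, width_range = c(18, 80),
    amp_meanlog = log(1.5), amp_sdlog = 0.3, base_rate = 0.02,
    untuned_meanlog = log(0.2), untuned_sdlog = 0.5,
    onset_ramp_laps = 4L, onset_geom_p = 0.35, max_onset_lap = 8L,
    com_drift_cm_per_lap = 0,
    jitter_sdlog = 0.25, jitter_sdlog_destab_zoneB = 0.6,
    object_width = 4, object_offset_range = c(2, 8),
    ca_decay_s = 1.5, ca_amp = 20, soma_base = 100, npil_base = 50,
    noise_sd_soma = 2, noise_sd_npil = 1,
    precision_target_fam = 0.40, precision_target_nov = 0.27,
    rate_ceiling = 25
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("scenario_config: unknown option(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  if (scenario == "shifting" && !("object_locked_frac" %in% names(dots)))
    cfg$object_locked_frac <- 0.08
  structure(cfg, class = "ScenarioConfig")
}

# geometry of one environment; tunnel midpoint is position 0 (= lap start)
make_env_geometry <- function(name, track_length, reward_bins, n_bins = 100L,
                              with_zones = FALSE, lap_object_table = NULL) {
  bin_size <- track_length / n_bins
  centers <- (seq_len(n_bins) - 0.5) * bin_size
  tunnel <- which(pmin(centers, track_length - centers) < 15)
  zone_a <- zone_b <- slots <- NULL
  if (with_zones) {
    # zone A: 50 bins centered on the tunnel; zone B: the opposite 50
    zone_a <- ((91:140) - 1L) %% n_bins + 1L
    zone_b <- 41:90
    slots <- 160 + (0:5) * 31.5   # cm; >= track_length/12 apart, inside zone B
  }
  environment_spec(name = name, track_length = track_length, n_bins = n_bins,
                   reward_bins = reward_bins, tunnel_bins = tunnel,
                   zone_a = zone_a, zone_b = zone_b, object_slots = slots,
                   lap_object_table = lap_object_table)
}

#' Generate a per-lap object-to-slot assignment table
#'
#' Each lap assigns the 4 zone-B objects injectively to the 6 slots; in the
#' shifting/destabilized configurations the draw is uniform over the 360
#' ordered arrangements and redrawn at the beginning of every lap, while a
#' fixed table repeats its first row.
#'
#' @param n_laps number of laps.
#' @param shifting logical; FALSE produces a constant table.
#' @param n_objects,n_slots task geometry (4 and 6).
#' @return n_laps x n_objects integer matrix of slot indices.
#' @export
generate_object_table <- function(n_laps, shifting = TRUE, n_objects = 4L,
                                  n_slots = 6L) {
  if (!shifting) {
    row <- sample.int(n_slots, n_objects)
    return(matrix(row, n_laps, n_objects, byrow = TRUE))
  }
  t(vapply(seq_len(n_laps), function(l) sample.int(n_slots, n_objects),
           integer(n_objects)))
}

#' Generate a running trajectory through one or two environments
#'
#' Speed follows a mean-reverting process around ~15 cm/s with
#' exponentially distributed pauses (sub-1 cm/s) at a configurable hazard;
#' position integrates the speed and wraps at the track length, the lap
#' index incrementing exactly at the wrap (tunnel midpoint). In the
#' teleportation scenario the environment label switches at the wrap that
#' ends the last familiar lap, so the switch sample always lies in tunnel
#' bins.
#'
#' @param cfg a [scenario_config()]; RNG state is used as-is (seed the
#'   caller).
#' @return List: `time`, `position`, `velocity`, `lap` (global), `env`
#'   (label per sample), `blocks` (per environment: name, track_length,
#'   lap range).
#' @export
generate_trajectory <- function(cfg) {
  blocks <- if (cfg$scenario == "teleportation") list(
    list(name = "familiar", len = cfg$track_length_fam, laps = cfg$n_laps_fam),
    list(name = "novel", len = cfg$track_length_nov, laps = cfg$n_laps_nov)
  ) else if (cfg$scenario == "destabilized") list(
    list(name = "object_env", len = cfg$track_length_obj,
         laps = cfg$n_laps_pre + cfg$n_laps_destab)
  ) else list(
    list(name = "object_env", len = cfg$track_length_obj, laps = cfg$n_laps)
  )
  dt <- 1 / cfg$frame_rate_hz
  time <- position <- velocity <- numeric(0)
  lap <- integer(0); envlab <- character(0)
  t_now <- 0; v <- cfg$mean_speed; lap_global <- 0L
  pause_left <- 0
  for (b in seq_along(blocks)) {
    blk <- blocks[[b]]
    pos <- 0; laps_done <- 0L
    lap_global <- lap_global + 1L
    while (laps_done < blk$laps) {
      if (pause_left > 0) {
        pause_left <- pause_left - dt
        v_eff <- cfg$pause_speed
      } else {
        if (stats::runif(1) < cfg$pause_hazard * dt)
          pause_left <- stats::rexp(1, 1 / cfg$pause_mean_s)
        v <- v + cfg$speed_theta * (cfg$mean_speed - v) * dt +
          cfg$speed_sd * sqrt(dt) * stats::rnorm(1)
        v <- min(max(v, 2), 60)
        v_eff <- v
      }
      time <- c(time, t_now); position <- c(position, pos)
      velocity <- c(velocity, v_eff); lap <- c(lap, lap_global)
      envlab <- c(envlab, blk$name)
      pos <- pos + v_eff * dt
      t_now <- t_now + dt
      if (pos >= blk$len) {
        pos <- pos - blk$len
        laps_done <- laps_done + 1L
        if (laps_done < blk$laps) lap_global <- lap_global + 1L
      }
    }
  }
  list(time = time, position = position, velocity = velocity, lap = lap,
       env = envlab,
       blocks = lapply(blocks, function(b) list(name = b$name,
                                                track_length = b$len,
                                                n_laps = b$laps)))
}

# draw per-cell ground truth
draw_ground_truth <- function(cfg) {
  n <- cfg$n_cells
  truth <- data.frame(cell = seq_len(n), kind = "untuned",
                      base_rate = exp(stats::rnorm(n, cfg$untuned_meanlog,
                                                   cfg$untuned_sdlog)),
                      amp = NA_real_, width_cm = NA_real_,
                      has_fam = FALSE, has_nov = FALSE,
                      center_fam_cm = NA_real_, center_nov_cm = NA_real_,
                      onset_fam = NA_integer_, onset_nov = NA_integer_,
                      com_drift = cfg$com_drift_cm_per_lap,
                      object_id = NA_integer_, object_offset_cm = NA_real_,
                      stringsAsFactors = FALSE)
  clip <- function(x, r) pmin(pmax(x, r[1]), r[2])
  if (cfg$scenario == "teleportation") {
    # independent allocation with an optional planted overlap excess
    has_fam <- stats::runif(n) < cfg$p_field_fam
    # P(both) = p_fam * q1 = p_fam * p_nov + overlap_excess;
    # q0 keeps the marginal P(nov) at p_field_nov
    q1 <- min(1, cfg$p_field_nov +
                if (cfg$p_field_fam > 0) cfg$overlap_excess / cfg$p_field_fam
              else 0)
    q0 <- max(0, (cfg$p_field_nov - cfg$p_field_fam * q1) /
                max(1 - cfg$p_field_fam, 1e-12))
    has_nov <- stats::runif(n) < ifelse(has_fam, q1, q0)
    tuned <- has_fam | has_nov
    truth$kind[tuned] <- "pcc"
    truth$has_fam <- has_fam
    truth$has_nov <- has_nov
    truth$center_fam_cm[has_fam] <- stats::runif(sum(has_fam), 0,
                                                 cfg$track_length_fam)
    truth$center_nov_cm[has_nov] <- stats::runif(sum(has_nov), 0,
                                                 cfg$track_length_nov)
    truth$onset_fam[has_fam] <- 1L
    truth$onset_nov[has_nov] <- pmin(1L + stats::rgeom(sum(has_nov),
                                                       cfg$onset_geom_p),
                                     cfg$max_onset_lap)
  } else {
    n_obj <- max(0L, round(cfg$object_locked_frac * n))
    n_pcc <- round(cfg$p_field * n)
    kinds <- rep("untuned", n)
    kinds[seq_len(n_pcc)] <- "pcc"
    if (n_obj > 0) kinds[n_pcc + seq_len(n_obj)] <- "object_locked"
    kinds <- sample(kinds)
    truth$kind <- kinds
    pcc <- kinds == "pcc"
    truth$has_fam[pcc] <- TRUE
    truth$center_fam_cm[pcc] <- stats::runif(sum(pcc), 0, cfg$track_length_obj)
    truth$onset_fam[pcc] <- 1L
    obj <- kinds == "object_locked"
    truth$object_id[obj] <- sample.int(4L, sum(obj), replace = TRUE)
    truth$object_offset_cm[obj] <- stats::runif(sum(obj),
                                                cfg$object_offset_range[1],
                                                cfg$object_offset_range[2])
  }
  tuned <- truth$kind != "untuned"
  truth$amp[tuned] <- exp(stats::rnorm(sum(tuned), cfg$amp_meanlog,
                                       cfg$amp_sdlog))
  truth$width_cm[tuned] <- clip(stats::rnorm(sum(tuned), cfg$width_mean,
                                             cfg$width_sd), cfg$width_range)
  truth$base_rate[tuned] <- cfg$base_rate
  truth
}

#' Generate the neural population for a trajectory
#'
#' Instantaneous rate per cell = baseline + Gaussian field terms (in
#' circular position for place cells, with `width_cm` the field FWHM; in
#' distance-behind-object for object-locked cells following the per-lap
#' object table, with `object_width` the Gaussian sigma in cm), scaled by a
#' per-lap gain (onset ramp times lognormal jitter) with optional
#' center-of-mass drift per lap. Events are Poisson(rate * dt);
#' fluorescence convolves the events with a 1.5 s exponential kernel and
#' adds Gaussian noise plus a shared slow neuropil component; the
#' deconvolved channel carries the noiseless events.
#'
#' @param cfg a [scenario_config()].
#' @param truth ground-truth data.frame from the generator.
#' @param traj trajectory list from [generate_trajectory()].
#' @param object_table per-lap slot table (or NULL), rows = global laps of
#'   the object environment.
#' @param slots_cm slot positions in cm (for object-locked cells).
#' @param epochs_by_lap character vector naming the configuration epoch of
#'   each global lap (for epoch-specific gain jitter).
#' @param zones optional zone list for epoch-specific zone-B jitter.
#' @return List: `rate`, `deconv`, `fluo_soma`, `fluo_neuropil` (cells x
#'   samples), `lap_gain` (cells x laps).
#' @export
generate_population <- function(cfg, truth, traj, object_table = NULL,
                                slots_cm = NULL, epochs_by_lap = NULL,
                                zones = NULL) {
  n <- cfg$n_cells
  ns <- length(traj$time)
  dt <- 1 / cfg$frame_rate_hz
  n_laps_total <- max(traj$lap)
  # per-sample environment block info
  blk_len <- stats::setNames(vapply(traj$blocks, `[[`, numeric(1),
                                    "track_length"),
                             vapply(traj$blocks, `[[`, character(1), "name"))
  len_s <- unname(blk_len[traj$env])
  # lap index local to each environment block
  lap_env <- traj$lap
  for (b in traj$blocks) {
    in_b <- traj$env == b$name
    lap_env[in_b] <- traj$lap[in_b] - min(traj$lap[in_b]) + 1L
  }
  rate <- matrix(cfg$base_rate, n, ns)
  lap_gain <- matrix(1, n, n_laps_total)
  bin_size_obj <- cfg$track_length_obj / 100
  for (i in seq_len(n)) {
    tr <- truth[i, ]
    if (tr$kind == "untuned") {
      rate[i, ] <- tr$base_rate
      next
    }
    # per-lap gain: epoch-specific lognormal jitter; zone-B cells get the
    # destabilized jitter during destabilized laps
    sdlog <- rep(cfg$jitter_sdlog, n_laps_total)
    if (!is.null(epochs_by_lap) && tr$kind == "pcc" && !is.null(zones)) {
      pk_bin <- position_to_bin(tr$center_fam_cm, cfg$track_length_obj, 100L)
      if (pk_bin %in% zones$zone_b)
        sdlog[epochs_by_lap == "destabilized"] <- cfg$jitter_sdlog_destab_zoneB
    }
    lap_gain[i, ] <- exp(stats::rnorm(n_laps_total, 0, 1) * sdlog -
                           sdlog^2 / 2)
    r <- rep(tr$base_rate, ns)
    sigma <- tr$width_cm / 2.355   # width_cm is the field FWHM
    if (tr$kind == "pcc") {
      for (b in traj$blocks) {
        env_has <- if (b$name == "novel") tr$has_nov else tr$has_fam
        if (!env_has) next
        center0 <- if (b$name == "novel") tr$center_nov_cm else tr$center_fam_cm
        onset <- if (b$name == "novel") tr$onset_nov else tr$onset_fam
        in_b <- which(traj$env == b$name)
        le <- lap_env[in_b]
        act <- le >= onset
        if (!any(act)) next
        idx <- in_b[act]
        laps_since <- le[act] - onset
        center <- (center0 + tr$com_drift * laps_since) %% b$track_length
        d <- circ_diff_cm(traj$position[idx], center, b$track_length)
        ramp <- pmin(1, (laps_since + 1) / cfg$onset_ramp_laps)
        g <- lap_gain[i, traj$lap[idx]] * ramp
        r[idx] <- r[idx] + tr$amp * g * exp(-d^2 / (2 * sigma^2))
      }
    } else {  # object_locked: fires a fixed distance behind its object
      stopifnot(!is.null(object_table), !is.null(slots_cm))
      in_b <- which(traj$env == "object_env")
      le <- lap_env[in_b]
      slot_idx <- object_table[cbind(le, tr$object_id)]
      center <- (slots_cm[slot_idx] - tr$object_offset_cm) %%
        cfg$track_length_obj
      d <- circ_diff_cm(traj$position[in_b], center, cfg$track_length_obj)
      g <- lap_gain[i, traj$lap[in_b]]
      r[in_b] <- r[in_b] + tr$amp * g * exp(-d^2 / (2 * cfg$object_width^2))
    }
    rate[i, ] <- pmin(r, cfg$rate_ceiling)
  }
  events <- matrix(stats::rpois(n * ns, rate * dt), n, ns)
  # calcium kernel: instantaneous rise, 1.5 s exponential decay
  klen <- ceiling(5 * cfg$ca_decay_s * cfg$frame_rate_hz)
  kern <- exp(-(0:(klen - 1)) * dt / cfg$ca_decay_s)
  conv1 <- function(x) stats::filter(x, kern, method = "convolution",
                                     sides = 1)
  npil_shared <- cfg$npil_base +
    5 * sin(2 * pi * traj$time / max(traj$time, 1)) +
    cumsum(stats::rnorm(ns, 0, 0.02))
  soma <- matrix(0, n, ns)
  npil <- matrix(0, n, ns)
  for (i in seq_len(n)) {
    cv <- as.numeric(conv1(events[i, ]))
    # head of the convolution (filter() leaves NAs): direct computation
    head_n <- min(klen - 1L, ns)
    if (head_n > 0) {
      ev <- events[i, seq_len(head_n)]
      cv[seq_len(head_n)] <- vapply(seq_len(head_n), function(t)
        sum(ev[seq_len(t)] * kern[t:1]), numeric(1))
    }
    npil[i, ] <- npil_shared + stats::rnorm(ns, 0, cfg$noise_sd_npil)
    soma[i, ] <- cfg$soma_base + cfg$ca_amp * cv + 0.7 * npil_shared +
      stats::rnorm(ns, 0, cfg$noise_sd_soma)
  }
  list(rate = rate, deconv = events, fluo_soma = soma, fluo_neuropil = npil,
       lap_gain = lap_gain)
}

#' Generate lick times calibrated to a target precision
#'
#' Scored (non-post) bins are licked independently per lap: anticipatory
#' bins with probability `p_a`, other scored bins with `p_n = 0.1`, where
#' `p_a` solves `10 p_a / (10 p_a + 80 p_n) = precision_target`; post-reward
#' bins are licked with probability 0.9 (consumption). Anticipatory
#' lick-bins emit a 2-lick burst to exercise burst-invariance. Reward
#' delivery times (first sample in each reward bin per lap) are returned
#' alongside.
#'
#' @param cfg a [scenario_config()].
#' @param traj trajectory list.
#' @param env an `EnvironmentSpec` (reward bins + geometry).
#' @param precision_target expected measured precision in `[0, 1]`.
#' @return List: `lick_times`, `reward_times`.
#' @export
generate_licks <- function(cfg, traj, env, precision_target) {
  stopifnot(precision_target >= 0, precision_target <= 1)
  w <- lick_windows(env$reward_bins, env$n_bins)
  # precision = 10 p_a / (10 p_a + 80 p_n)  =>  p_a = 8 p_n T / (1 - T)
  p_n <- if (precision_target >= 1) 0 else 0.1
  p_a <- if (precision_target >= 1) 0.6 else
    min(1, 8 * p_n * precision_target / (1 - precision_target))
  in_env <- which(traj$env == env$name)
  bins <- position_to_bin(traj$position[in_env], env$track_length, env$n_bins)
  laps <- traj$lap[in_env]
  lick_times <- numeric(0); reward_times <- numeric(0)
  first_time <- function(lap_id, bin) {
    k <- in_env[laps == lap_id & bins == bin]
    if (length(k)) traj$time[k[1]] else NA_real_
  }
  scored_other <- setdiff(setdiff(seq_len(env$n_bins), w$post), w$anticipatory)
  for (lap_id in unique(laps)) {
    for (b in w$anticipatory) if (stats::runif(1) < p_a) {
      t0 <- first_time(lap_id, b)
      if (!is.na(t0)) lick_times <- c(lick_times, t0, t0 + 0.04)
    }
    for (b in scored_other) if (stats::runif(1) < p_n) {
      t0 <- first_time(lap_id, b)
      if (!is.na(t0)) lick_times <- c(lick_times, t0)
    }
    for (b in w$post) if (stats::runif(1) < 0.9) {
      t0 <- first_time(lap_id, b)
      if (!is.na(t0)) lick_times <- c(lick_times, t0)
    }
    for (rb in env$reward_bins) {
      t0 <- first_time(lap_id, rb)
      if (!is.na(t0)) reward_times <- c(reward_times, t0)
    }
  }
  list(lick_times = sort(lick_times), reward_times = sort(reward_times))
}

#' Simulate a complete session with planted ground truth
#'
#' Drives [generate_trajectory()], [generate_object_table()],
#' [generate_population()] and [generate_licks()] under a single seeded RNG
#' and assembles a `SessionRecording` (with dF/F precomputed via
#' [compute_dff()] by default), its `EnvironmentSpec`s, and the ground
#' truth needed for parameter-recovery tests. Two runs with the same config
#' are bit-identical.
#'
#' @param cfg a [scenario_config()].
#' @param compute_dff_channel fill `rec$dff` via [compute_dff()] (default
#'   TRUE).
#' @return List: `rec` (`SessionRecording`), `truth` (data.frame),
#'   `epochs_by_lap` (object scenarios), `lap_gain`.
#' @export
simulate_session <- function(cfg, compute_dff_channel = TRUE) {
  stopifnot(inherits(cfg, "ScenarioConfig"))
  set.seed(cfg$seed)
  traj <- generate_trajectory(cfg)
  object_table <- NULL; epochs_by_lap <- NULL
  envs <- list()
  if (cfg$scenario == "teleportation") {
    envs$familiar <- make_env_geometry("familiar", cfg$track_length_fam,
                                       reward_bins = c(25L, 70L))
    envs$novel <- make_env_geometry("novel", cfg$track_length_nov,
                                    reward_bins = c(30L, 80L))
  } else {
    n_laps_total <- max(traj$lap)
    if (cfg$scenario == "destabilized") {
      pre <- generate_object_table(cfg$n_laps_pre, shifting = FALSE)
      dest <- generate_object_table(cfg$n_laps_destab, shifting = TRUE)
      object_table <- rbind(pre, dest)
      epochs_by_lap <- c(rep("pre", cfg$n_laps_pre),
                         rep("destabilized", cfg$n_laps_destab))
    } else {
      object_table <- generate_object_table(n_laps_total,
                                            shifting = cfg$scenario == "shifting")
      epochs_by_lap <- rep(cfg$scenario, n_laps_total)
    }
    envs$object_env <- make_env_geometry("object_env", cfg$track_length_obj,
                                         reward_bins = c(20L, 70L),
                                         with_zones = TRUE,
                                         lap_object_table = object_table)
  }
  truth <- draw_ground_truth(cfg)
  zones <- if (!is.null(envs$object_env))
    list(zone_a = envs$object_env$zone_a, zone_b = envs$object_env$zone_b)
  pop <- generate_population(cfg, truth, traj, object_table = object_table,
                             slots_cm = envs[[length(envs)]]$object_slots,
                             epochs_by_lap = epochs_by_lap, zones = zones)
  licks <- list(lick_times = numeric(0), reward_times = numeric(0))
  for (nm in names(envs)) {
    tgt <- if (nm == "novel") cfg$precision_target_nov else
      cfg$precision_target_fam
    lk <- generate_licks(cfg, traj, envs[[nm]], tgt)
    licks$lick_times <- c(licks$lick_times, lk$lick_times)
    licks$reward_times <- c(licks$reward_times, lk$reward_times)
  }
  rec <- session_recording(
    time = traj$time, position = traj$position, velocity = traj$velocity,
    lap = traj$lap, env = traj$env, frame_rate_hz = cfg$frame_rate_hz,
    fluo_soma = pop$fluo_soma, fluo_neuropil = pop$fluo_neuropil,
    deconv = pop$deconv,
    lick_times = sort(licks$lick_times),
    reward_times = sort(licks$reward_times), envs = envs
  )
  if (compute_dff_channel) {
    rec$dff <- suppressWarnings(
      compute_dff(rec$fluo_soma, rec$fluo_neuropil,
                  preprocess_config(), cfg$frame_rate_hz))
  }
  list(rec = rec, truth = truth, epochs_by_lap = epochs_by_lap,
       lap_gain = pop$lap_gain, trajectory_blocks = traj$blocks)
}
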