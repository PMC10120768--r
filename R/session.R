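# Session data model: one imaging session = time-aligned traces, trajectory,
# events, and one EnvironmentSpec per visited environment.

#' Construct a SessionRecording
#'
#' The central per-session container: cell-by-sample fluorescence (soma and
#' optional surrounding-neuropil channels, or pre-computed dF/F), an optional
#' deconvolved event channel, the animal's trajectory on the circular track,
#' lick and reward event times, and a per-sample environment label.
#'
#' @param time sample times in seconds, strictly increasing.
#' @param position position along the track in cm, in `[0, track_length)`.
#' @param velocity running speed in cm/s.
#' @param lap 1-based lap index per sample, non-decreasing within an
#'   environment and incrementing only at the position wrap (lap start is the
#'   tunnel midpoint).
#' @param env environment label per sample (character).
#' @param frame_rate_hz imaging frame rate in samples/s (6-8 Hz typical).
#' @param fluo_soma,fluo_neuropil cells x samples fluorescence matrices
#'   (arbitrary units); `fluo_neuropil` optional.
#' @param dff optional cells x samples relative-fluorescence matrix; at least
#'   one of `fluo_soma`, `dff` must be supplied.
#' @param deconv optional cells x samples nonnegative deconvolved event
#'   amplitudes (used for spatial information and decoding).
#' @param lick_times,reward_times event times in seconds.
#' @param envs named list of [environment_spec()] objects, one per label
#'   appearing in `env`.
#' @return An object of class `SessionRecording`.
#' @export
session_recording <- function(time, position, velocity, lap, env, frame_rate_hz,
                              fluo_soma = NULL, fluo_neuropil = NULL,
                              dff = NULL, deconv = NULL,
                              lick_times = numeric(), reward_times = numeric(),
                              envs = list()) {
  rec <- structure(list(
    time = as.numeric(time), position = as.numeric(position),
    velocity = as.numeric(velocity), lap = as.integer(lap),
    env = as.character(env), frame_rate_hz = as.numeric(frame_rate_hz),
    fluo_soma = fluo_soma, fluo_neuropil = fluo_neuropil,
    dff = dff, deconv = deconv,
    lick_times = as.numeric(lick_times), reward_times = as.numeric(reward_times),
    envs = envs
  ), class = "SessionRecording")
  validate_session(rec)
  rec
}

#' Construct an EnvironmentSpec
#'
#' Geometry and task layout of one circular-track environment: track length,
#' binning (100 bins by default, so bin size is 3-5 cm depending on the
#' track), the two hidden reward sites, the 30 cm tunnel that defines the lap
#' start (its midpoint is position 0), optional A/B zones and the six
#' object slots of zone B with a per-lap object-to-slot assignment table.
#'
#' @param name environment label.
#' @param track_length track circumference in cm (314-503 in practice).
#' @param n_bins number of position bins (default 100).
#' @param reward_bins integer vector of length 2, 1-based bin indices of the
#'   reward sites.
#' @param tunnel_bins 1-based bin indices covered by the 30 cm tunnel.
#' @param zone_a,zone_b optional 1-based bin index vectors of the two zones.
#' @param object_slots optional numeric vector of 6 slot positions (cm) in
#'   zone B.
#' @param lap_object_table optional laps x 4 integer matrix giving, per lap,
#'   the slot (1-6) occupied by each of the 4 zone-B objects; rows must be
#'   injective.
#' @return An object of class `EnvironmentSpec`.
#' @export
environment_spec <- function(name, track_length, n_bins = 100L,
                             reward_bins = integer(), tunnel_bins = integer(),
                             zone_a = NULL, zone_b = NULL,
                             object_slots = NULL, lap_object_table = NULL) {
  spec <- structure(list(
    name = as.character(name), track_length = as.numeric(track_length),
    n_bins = as.integer(n_bins), reward_bins = as.integer(reward_bins),
    tunnel_bins = as.integer(tunnel_bins),
    zone_a = if (is.null(zone_a)) NULL else as.integer(zone_a),
    zone_b = if (is.null(zone_b)) NULL else as.integer(zone_b),
    object_slots = if (is.null(object_slots)) NULL else as.numeric(object_slots),
    lap_object_table = if (is.null(lap_object_table)) NULL else
      matrix(as.integer(lap_object_table), nrow = nrow(lap_object_table))
  ), class = "EnvironmentSpec")
  if (!is.null(spec$lap_object_table)) {
    inj <- apply(spec$lap_object_table, 1, function(r) !anyDuplicated(r))
    if (!all(inj))
      stop("lap_object_table: object-to-slot assignment must be injective on every lap")
  }
  spec
}

#' @export
print.SessionRecording <- function(x, ...) {
  cat(sprintf("<SessionRecording> %d samples @ %.1f Hz, %d cells, envs: %s\n",
              length(x$time), x$frame_rate_hz, n_cells(x),
              paste(names(x$envs), collapse = ", ")))
  invisible(x)
}

#' Number of cells in a session
#' @param rec a `SessionRecording`.
#' @export
n_cells <- function(rec) {
  for (f in c("fluo_soma", "dff", "deconv"))
    if (!is.null(rec[[f]])) return(nrow(rec[[f]]))
  0L
}

#' Validate SessionRecording invariants
#'
#' Checks monotone time, positions within each environment's track, lap
#' indices that increment only at the position wrap, matching cell
#' dimensions, presence of at least one of `fluo_soma`/`dff`, nonnegative
#' `deconv`, and that environment switches happen inside tunnel bins.
#'
#' @param rec a `SessionRecording`.
#' @return `rec`, invisibly; stops with a validation error otherwise.
#' @export
validate_session <- function(rec) {
  n <- length(rec$time)
  for (f in c("position", "velocity", "lap", "env"))
    if (length(rec[[f]]) != n)
      stop(sprintf("validation error: length(%s) != length(time)", f))
  if (n > 1 && any(diff(rec$time) <= 0))
    stop("validation error: time must be strictly increasing")
  if (is.null(rec$fluo_soma) && is.null(rec$dff))
    stop("format error: at least one of fluo_soma, dff is required")
  ncells <- NULL
  for (f in c("fluo_soma", "fluo_neuropil", "dff", "deconv")) {
    m <- rec[[f]]
    if (is.null(m)) next
    if (!is.matrix(m) || ncol(m) != n)
      stop(sprintf("format error: %s must be a cells x samples matrix", f))
    if (is.null(ncells)) ncells <- nrow(m)
    if (nrow(m) != ncells)
      stop(sprintf("validation error: %s disagrees on the cell dimension", f))
  }
  if (!is.null(rec$deconv) && any(rec$deconv < 0, na.rm = TRUE))
    stop("validation error: deconv must be >= 0 everywhere")
  if (n > 1 && any(diff(rec$lap) < 0 & rec$env[-1] == rec$env[-n]))
    stop("validation error: lap index must be non-decreasing within an environment")
  for (nm in unique(rec$env)) {
    spec <- rec$envs[[nm]]
    if (is.null(spec)) next
    pos <- rec$position[rec$env == nm]
    if (any(pos < 0 | pos >= spec$track_length))
      stop(sprintf("validation error: position outside [0, track_length) in env %s", nm))
  }
  # environment switches must occur within tunnel bins
  if (n > 1) {
    sw <- which(rec$env[-1] != rec$env[-n]) + 1L
    for (i in sw) {
      spec <- rec$envs[[rec$env[i]]]
      if (is.null(spec) || !length(spec$tunnel_bins)) next
      b <- position_to_bin(rec$position[i], spec$track_length, spec$n_bins)
      if (!(b %in% spec$tunnel_bins))
        stop("validation error: environment switch outside tunnel bins")
    }
  }
  invisible(rec)
}

env_spec_to_list <- function(spec) {
  out <- unclass(spec)
  if (!is.null(out$lap_object_table)) {
    out$lap_object_table <- apply(out$lap_object_table, 1, identity,
                                  simplify = FALSE)
  }
  out
}

env_spec_from_list <- function(lst) {
  tab <- lst$lap_object_table
  if (!is.null(tab)) tab <- do.call(rbind, lapply(tab, as.integer))
  environment_spec(
    name = lst$name, track_length = lst$track_length, n_bins = lst$n_bins,
    reward_bins = lst$reward_bins, tunnel_bins = lst$tunnel_bins,
    zone_a = lst$zone_a, zone_b = lst$zone_b,
    object_slots = lst$object_slots, lap_object_table = tab
  )
}

#' Write a session to disk
#'
#' Two interchangeable container layouts are supported. `format = "h5"`
#' writes a single HDF5 file with datasets `/time`, `/position`, `/velocity`,
#' `/lap`, `/env`, `/fluo_soma`, `/fluo_neuropil`, `/dff`, `/deconv`,
#' `/licks`, `/rewards` and a YAML attribute block holding `frame_rate_hz`
#' and the environment specs. `format = "csv"` writes a directory of
#' RFC-4180 CSV files with identical names plus `environment.yaml`, for
#' toolchain-free inspection.
#'
#' @param rec a `SessionRecording`.
#' @param path output file (h5) or directory (csv).
#' @param format `"h5"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_session <- function(rec, path, format = c("h5", "csv")) {
  format <- match.arg(format)
  validate_session(rec)
  meta <- list(frame_rate_hz = rec$frame_rate_hz,
               envs = lapply(rec$envs, env_spec_to_list))
  meta_yaml <- yaml::as.yaml(meta)
  if (format == "h5") {
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    h5w <- function(name, x) if (!is.null(x)) rhdf5::h5write(x, path, name)
    h5w("time", rec$time); h5w("position", rec$position)
    h5w("velocity", rec$velocity); h5w("lap", rec$lap); h5w("env", rec$env)
    h5w("fluo_soma", rec$fluo_soma); h5w("fluo_neuropil", rec$fluo_neuropil)
    h5w("dff", rec$dff); h5w("deconv", rec$deconv)
    h5w("licks", rec$lick_times); h5w("rewards", rec$reward_times)
    h5w("meta_yaml", meta_yaml)
    rhdf5::h5closeAll()
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    ts <- data.frame(time = rec$time, position = rec$position,
                     velocity = rec$velocity, lap = rec$lap, env = rec$env)
    utils::write.csv(ts, file.path(path, "timeseries.csv"), row.names = FALSE)
    wmat <- function(name, m) {
      if (is.null(m)) return()
      utils::write.csv(as.data.frame(t(m)), file.path(path, name),
                       row.names = FALSE)
    }
    wmat("fluo_soma.csv", rec$fluo_soma)
    wmat("fluo_neuropil.csv", rec$fluo_neuropil)
    wmat("dff.csv", rec$dff); wmat("deconv.csv", rec$deconv)
    utils::write.csv(data.frame(time = rec$lick_times),
                     file.path(path, "licks.csv"), row.names = FALSE)
    utils::write.csv(data.frame(time = rec$reward_times),
                     file.path(path, "rewards.csv"), row.names = FALSE)
    writeLines(meta_yaml, file.path(path, "environment.yaml"))
  }
  invisible(path)
}

#' Read a session container written by [write_session()]
#'
#' The layout is auto-detected: a directory is read as the CSV fallback, a
#' file as HDF5. Missing mandatory arrays raise a format error naming the
#' array; all [validate_session()] invariants are enforced after reading.
#'
#' @param path session file or directory.
#' @return A `SessionRecording` (with its `EnvironmentSpec`s in `$envs`).
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stop(sprintf("format error: no such path: %s", path))
  if (dir.exists(path)) {
    tsf <- file.path(path, "timeseries.csv")
    if (!file.exists(tsf)) stop("format error: missing mandatory array: timeseries")
    ts <- utils::read.csv(tsf, stringsAsFactors = FALSE)
    rmat <- function(name) {
      f <- file.path(path, name)
      if (!file.exists(f)) return(NULL)
      t(as.matrix(utils::read.csv(f)))
    }
    meta <- yaml::read_yaml(file.path(path, "environment.yaml"))
    lick <- utils::read.csv(file.path(path, "licks.csv"))$time
    rew <- utils::read.csv(file.path(path, "rewards.csv"))$time
    fs <- rmat("fluo_soma.csv"); fn <- rmat("fluo_neuropil.csv")
    dff <- rmat("dff.csv"); dec <- rmat("deconv.csv")
  } else {
    ls <- rhdf5::h5ls(path)$name
    need <- c("time", "position", "velocity", "lap", "env")
    miss <- setdiff(need, ls)
    if (length(miss))
      stop(sprintf("format error: missing mandatory array: %s", miss[1]))
    h5r <- function(name) if (name %in% ls) rhdf5::h5read(path, name) else NULL
    ts <- data.frame(time = as.numeric(h5r("time")),
                     position = as.numeric(h5r("position")),
                     velocity = as.numeric(h5r("velocity")),
                     lap = as.integer(h5r("lap")),
                     env = as.character(h5r("env")))
    fs <- h5r("fluo_soma"); fn <- h5r("fluo_neuropil")
    dff <- h5r("dff"); dec <- h5r("deconv")
    lick <- as.numeric(h5r("licks")); rew <- as.numeric(h5r("rewards"))
    meta <- yaml::yaml.load(as.character(h5r("meta_yaml")))
    rhdf5::h5closeAll()
  }
  if (is.null(fs) && is.null(dff))
    stop("format error: missing mandatory array: one of fluo_soma, dff")
  session_recording(
    time = ts$time, position = ts$position, velocity = ts$velocity,
    lap = ts$lap, env = ts$env, frame_rate_hz = meta$frame_rate_hz,
    fluo_soma = fs, fluo_neuropil = fn, dff = dff, deconv = dec,
    lick_times = lick %||% numeric(), reward_times = rew %||% numeric(),
    envs = lapply(meta$envs, env_spec_from_list)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Count active cells in a session
#'
#' A cell is active if it has at least one deconvolved event; when the
#' deconvolved channel is absent, at least one dF/F sample above 3
#' session-level standard deviations of that cell's trace.
#'
#' @param rec a `SessionRecording` (dF/F must be present if deconv is not).
#' @return Integer count.
#' @export
count_active_cells <- function(rec) {
  if (!is.null(rec$deconv)) return(sum(rowSums(rec$deconv > 0) > 0))
  if (is.null(rec$dff)) stop("count_active_cells: needs deconv or dff")
  mu <- rowMeans(rec$dff)
  sdv <- apply(rec$dff, 1, stats::sd)
  sum(rowSums(rec$dff - mu > 3 * sdv) > 0)
}

#' Session-level quality control
#'
#' A session passes only if every analyzed environment has at least 10 laps,
#' at least 50 active cells were detected, and the familiar-environment mean
#' decoder error is at most 30 cm. Always returns a verdict; each failed
#' rule contributes one reason.
#'
#' @param rec a `SessionRecording`.
#' @param decoder_err_familiar mean leave-one-lap-out decoder error in the
#'   familiar environment, cm.
#' @param min_laps,min_cells,max_decoder_err_cm inclusion thresholds.
#' @return List with `pass` (logical) and `reasons` (character vector).
#' @export
qc_session <- function(rec, decoder_err_familiar,
                       min_laps = 10L, min_cells = 50L,
                       max_decoder_err_cm = 30) {
  reasons <- character()
  lap_counts <- vapply(unique(rec$env), function(nm)
    length(unique(rec$lap[rec$env == nm])), integer(1))
  if (any(lap_counts < min_laps))
    reasons <- c(reasons, sprintf("fewer than %d laps in environment(s): %s",
                                  min_laps,
                                  paste(names(lap_counts)[lap_counts < min_laps],
                                        collapse = ", ")))
  nact <- count_active_cells(rec)
  if (nact < min_cells)
    reasons <- c(reasons, sprintf("only %d active cells (< %d)", nact, min_cells))
  if (decoder_err_familiar > max_decoder_err_cm)
    reasons <- c(reasons, sprintf("familiar decoder error %.1f cm > %.0f cm",
                                  decoder_err_familiar, max_decoder_err_cm))
  list(pass = length(reasons) == 0L, reasons = reasons)
}
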