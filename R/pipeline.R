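# End-to-end orchestration: QC -> preprocessing -> tuning -> decoding ->
# population dynamics -> remapping -> object tuning -> behavior, with tidy
# CSV outputs and a JSON manifest.

#' Pipeline configuration
#'
#' Nested blocks mirror the per-module configs; unspecified keys take the
#' documented defaults. The resolved config is written verbatim (as YAML)
#' into the output directory for provenance.
#'
#' @param preprocess,tuning,decoder,object_tuning named lists of overrides
#'   for [preprocess_config()], [tuning_config()], [decoder_config()],
#'   [object_tuning_config()].
#' @param stages character vector of stage names to run (default: all
#'   applicable).
#' @param seed global seed; per-stage RNGs are derived from it so disabling
#'   one stage never perturbs another.
#' @return A list of class `PipelineConfig`.
#' @export
pipeline_config <- function(preprocess = list(), tuning = list(),
                            decoder = list(), object_tuning = list(),
                            stages = c("qc", "preprocess", "tuning", "decode",
                                       "dynamics", "remap", "objects",
                                       "behavior"),
                            seed = 1L) {
  structure(list(
    preprocess = do.call(preprocess_config, preprocess),
    tuning = do.call(tuning_config, tuning),
    decoder = do.call(decoder_config, decoder),
    object_tuning = do.call(object_tuning_config, object_tuning),
    stages = stages, seed = as.integer(seed)
  ), class = "PipelineConfig")
}

stage_seed <- function(seed, stage) {
  # namespaced per-stage seeds, kept under 2^31
  (seed * 1000003L + sum(utf8ToInt(stage))) %% .Machine$integer.max
}

write_tidy <- function(df, out_dir, name) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 9))
  utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
}

#' Run the full analysis pipeline on one session
#'
#' Executes the enabled stages for every environment of the session and
#' writes one tidy CSV per product plus `manifest.json` (package version,
#' seed, per-file names) and `config.yaml`. A QC failure (when computable)
#' is recorded, not fatal. Outputs are pure functions of (session, config,
#' seed).
#'
#' @param rec a `SessionRecording`, or a path readable by [read_session()].
#' @param out_dir output directory (created).
#' @param cfg a [pipeline_config()].
#' @param epochs_by_lap optional configuration epoch per lap (enables the
#'   rate-variability stage on object sessions).
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(rec, out_dir, cfg = pipeline_config(),
                         epochs_by_lap = NULL) {
  if (is.character(rec)) rec <- read_session(rec)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(yaml::as.yaml(list(stages = cfg$stages, seed = cfg$seed,
                                preprocess = unclass(cfg$preprocess),
                                tuning = unclass(cfg$tuning),
                                decoder = unclass(cfg$decoder),
                                object_tuning = unclass(cfg$object_tuning))),
             file.path(out_dir, "config.yaml"))
  res <- list()
  on_stage <- function(s) s %in% cfg$stages
  env_names <- names(rec$envs)

  if (on_stage("preprocess") && is.null(rec$dff) && !is.null(rec$fluo_soma))
    rec$dff <- suppressWarnings(compute_dff(rec$fluo_soma, rec$fluo_neuropil,
                                            cfg$preprocess, rec$frame_rate_hz))

  binned <- list(); binned_dec <- list()
  for (nm in env_names) {
    binned[[nm]] <- bin_activity(rec, rec$envs[[nm]], cfg$preprocess, "dff")
    binned_dec[[nm]] <- bin_activity(rec, rec$envs[[nm]], cfg$preprocess,
                                     "deconv")
  }

  if (on_stage("decode")) {
    res$decode <- lapply(env_names, function(nm) tryCatch(
      decode_loocv(rec, rec$envs[[nm]], cfg$decoder, cfg$preprocess),
      error = function(e) NULL))
    names(res$decode) <- env_names
    for (nm in env_names) {
      d <- res$decode[[nm]]
      if (is.null(d)) next
      write_tidy(d$windows, out_dir, sprintf("decoder_windows_%s.csv", nm))
      write_tidy(d$laps, out_dir, sprintf("decoder_laps_%s.csv", nm))
    }
  }

  if (on_stage("qc")) {
    fam_err <- NA_real_
    if (!is.null(res$decode) && length(res$decode))
      fam_err <- res$decode[[1]]$mean_error_cm %||% NA_real_
    res$qc <- qc_session(rec, ifelse(is.na(fam_err), 0, fam_err))
    write_tidy(data.frame(pass = res$qc$pass,
                          reasons = paste(res$qc$reasons, collapse = "; ")),
               out_dir, "qc.csv")
  }

  if (on_stage("tuning")) {
    res$tuning <- list()
    for (nm in env_names) {
      zones <- if (!is.null(rec$envs[[nm]]$zone_a))
        list(zone_a = rec$envs[[nm]]$zone_a, zone_b = rec$envs[[nm]]$zone_b)
      res$tuning[[nm]] <- classify_pcc(binned[[nm]],
                                       si_binned = binned_dec[[nm]],
                                       cfg$tuning,
                                       seed = stage_seed(cfg$seed, "tuning"),
                                       zones = zones)
      tab <- res$tuning[[nm]]$table
      tab$env <- nm
      write_tidy(tab, out_dir, sprintf("pcc_%s.csv", nm))
    }
  }

  if (on_stage("dynamics") && !is.null(res$tuning)) {
    nm1 <- env_names[1]
    po <- order_by_peak(binned[[nm1]], seed = stage_seed(cfg$seed, "dynamics"))
    write_tidy(data.frame(cell = seq_along(po$order), rank = order(po$order),
                          peak_bin = po$peak_bin), out_dir,
               sprintf("peak_order_%s.csv", nm1))
    io <- in_out_ratio(binned[[nm1]])
    write_tidy(io, out_dir, sprintf("in_out_ratio_%s.csv", nm1))
    fl <- res$tuning[[nm1]]$fields
    if (length(fl)) {
      cs <- com_shift(binned[[nm1]], fl)
      write_tidy(cs$by_lap, out_dir, sprintf("com_shift_%s.csv", nm1))
      fs <- field_size_by_lap(binned[[nm1]], fl)
      write_tidy(fs$by_lap, out_dir, sprintf("field_size_%s.csv", nm1))
    }
    if (length(env_names) >= 2) {
      tc <- pv_timecourse(binned[[env_names[1]]], binned[[env_names[2]]],
                          "final_familiar")
      if (nrow(tc)) write_tidy(tc, out_dir, "pv_timecourse_final_familiar.csv")
      ga <- group_activity(binned[[env_names[1]]], binned[[env_names[2]]],
                           res$tuning[[env_names[1]]],
                           res$tuning[[env_names[2]]])
      if (!is.null(ga$series)) write_tidy(ga$series, out_dir,
                                          "group_activity.csv")
      res$group_activity <- ga
    }
  }

  if (on_stage("remap") && !is.null(res$tuning) && length(env_names) >= 2) {
    ov <- overlap_vs_expected(res$tuning[[env_names[1]]],
                              res$tuning[[env_names[2]]])
    write_tidy(ov$sessions, out_dir, "overlap_stats.csv")
    fc <- field_location_correlation(res$tuning[[env_names[1]]],
                                     res$tuning[[env_names[2]]])
    write_tidy(data.frame(r = fc$r, n = fc$n, p = fc$p), out_dir,
               "field_location_correlation.csv")
    res$overlap <- ov; res$field_corr <- fc
  }
  if (on_stage("remap") && !is.null(res$tuning) && !is.null(epochs_by_lap)) {
    nm <- env_names[1]
    zones <- list(zone_a = rec$envs[[nm]]$zone_a, zone_b = rec$envs[[nm]]$zone_b)
    ep <- epochs_by_lap[binned[[nm]]$lap_ids]
    rv <- lap_peak_variability(binned[[nm]], res$tuning[[nm]], ep, zones)
    if (nrow(rv$summary)) write_tidy(rv$summary, out_dir,
                                     "rate_variability.csv")
    sv <- speed_at_peak_variability(rec, rec$envs[[nm]], binned[[nm]],
                                    res$tuning[[nm]], ep, zones,
                                    cfg$preprocess)
    if (nrow(sv$summary)) write_tidy(sv$summary, out_dir,
                                     "speed_variability.csv")
    res$rate_variability <- rv; res$speed_variability <- sv
  }

  if (on_stage("objects")) {
    for (nm in env_names) {
      env <- rec$envs[[nm]]
      if (is.null(env$object_slots)) next
      res$objects <- classify_tuning(binned[[nm]], env, cfg$object_tuning,
                                     seed = stage_seed(cfg$seed, "objects"))
      write_tidy(res$objects$table, out_dir,
                 sprintf("object_tuning_%s.csv", nm))
    }
  }

  if (on_stage("behavior")) {
    rows <- list()
    for (nm in env_names) {
      if (!length(rec$envs[[nm]]$reward_bins)) next
      ls <- lick_precision(rec, rec$envs[[nm]])
      rows[[nm]] <- data.frame(env = nm, precision = ls$precision,
                               anticipatory = ls$anticipatory_count,
                               post_reward = ls$post_reward_count,
                               total = ls$total_count,
                               chance_level = ls$chance_level)
      res$behavior[[nm]] <- ls
    }
    if (length(rows)) write_tidy(do.call(rbind, rows), out_dir, "behavior.csv")
  }

  manifest <- list(
    package = "vrplace",
    version = as.character(utils::packageVersion("vrplace")),
    seed = cfg$seed, stages = cfg$stages,
    outputs = list.files(out_dir, pattern = "\\.csv$")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}
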