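# End-to-end orchestration: a validated nested config drives
# simulate -> physio -> cpca -> xcorr -> irf -> mcca -> events -> multiecho,
# with per-stage seed streams, serialized artifacts and provenance records.

#' Default pipeline configuration
#'
#' Returns the full nested configuration with every stage's defaults.
#' Unknown keys in a user configuration are rejected by
#' [validate_pipeline_config()]. Spatial smoothing defaults to 0 mm here
#' (the synthetic lattice has no spatial autocorrelation to preserve);
#' real-data runs should set the conventional 5 mm.
#'
#' @return Nested list of defaults.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    outdir = NULL,
    log_level = "info",
    stages = list(simulate = TRUE, physio = TRUE, cpca = TRUE, xcorr = TRUE,
                  irf = TRUE, mcca = FALSE, events = TRUE, multiecho = TRUE),
    synthetic = list(duration_s = 600, tr_s = 1, physio_fs_hz = 250,
                     n_voxels = 1000, noise_sd = 0.5, event_rate = 0.625,
                     echo_times_ms = c(13.7, 30, 47)),
    cpca = list(smoothing_fwhm_mm = 0, n_bins = 30, zscore_runs = TRUE),
    xcorr = list(max_lag_s = 30),
    irf = list(lag_min_s = -10, lag_max_s = 30, length_scale = 3,
               kernel_variance = 1),
    mcca = list(n_subjects = 8, n_perm = 199, window_s = c(0, 10),
                n_splines = 3, ridge_frac = 1e-6),
    events = list(window_s = 29, min_gap_s = 30, n_boot = 500),
    multiecho = list(retroicor_order = 2)
  )
}

#' Validate a pipeline configuration against the defaults
#'
#' Recursively merges `config` over [default_pipeline_config()]; any key
#' absent from the defaults raises an error naming the offending key.
#'
#' @param config Partial nested list of overrides.
#' @return The fully merged configuration.
#' @export
validate_pipeline_config <- function(config = list()) {
  merge_into <- function(template, user, path = "") {
    if (!is.list(user)) return(user)
    extra <- setdiff(names(user), names(template))
    if (length(extra) > 0) {
      stop(sprintf("unknown configuration key%s: %s",
                   if (length(extra) > 1) "s" else "",
                   paste0(path, extra, collapse = ", ")))
    }
    for (k in names(user)) {
      template[[k]] <- if (is.list(template[[k]]) && is.list(user[[k]])) {
        merge_into(template[[k]], user[[k]], paste0(path, k, "."))
      } else {
        user[[k]]
      }
    }
    template
  }
  merge_into(default_pipeline_config(), config)
}

# 31-bit multiplicative hash over the deparsed config, for provenance
# records (not cryptographic; just a stable run fingerprint)
config_hash <- function(config) {
  s <- paste(deparse(config), collapse = "")
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

pipeline_log <- function(level, cfg_level, ...) {
  levels <- c(debug = 1, info = 2, warn = 3, quiet = 4)
  if (levels[[level]] >= levels[[cfg_level]]) {
    message(sprintf("[%s] %s", level, sprintf(...)))
  }
}

#' Extract the standard feature panel from raw recordings
#'
#' Runs the full extraction chain on a named list of raw signals (as
#' produced by [generate_physio()] or read from BIDS physio files):
#' PPG -> heart rate and PPG amplitude; respiration -> respiratory volume;
#' skin conductance -> tonic SC; EEG -> alpha envelope; pupil passed
#' through. Everything is standardized onto the fMRI frame grid.
#'
#' @param signals Named list of [raw_physio_signal()]s (`ppg`,
#'   `respiration`, `skin_conductance`, `pupil`, `eeg`; all optional).
#' @param n_frames,tr_s Target fMRI grid.
#' @return Named list of [feature_series()].
#' @export
extract_features <- function(signals, n_frames, tr_s) {
  feats <- list()
  if (!is.null(signals$ppg)) {
    fs <- signals$ppg$fs_hz
    ns <- length(signals$ppg$samples)
    beats <- detect_ppg_peaks(signals$ppg)
    feats$heart_rate <- standardize_feature(
      heart_rate(beats, fs, ns), fs, n_frames, tr_s,
      name = "heart_rate", units = "bpm (z)")
    feats$ppg_amplitude <- standardize_feature(
      ppg_amplitude(beats, fs, ns), fs, n_frames, tr_s,
      name = "ppg_amplitude", units = "a.u. (z)")
    attr(feats$heart_rate, "beats") <- beats
  }
  if (!is.null(signals$respiration)) {
    fs <- signals$respiration$fs_hz
    feats$respiratory_volume <- standardize_feature(
      respiratory_volume(signals$respiration), fs, n_frames, tr_s,
      name = "respiratory_volume", units = "rad/s * a.u. (z)")
  }
  if (!is.null(signals$skin_conductance)) {
    fs <- signals$skin_conductance$fs_hz
    feats$tonic_sc <- standardize_feature(
      tonic_skin_conductance(signals$skin_conductance), fs, n_frames, tr_s,
      name = "tonic_sc", units = "uS (z)", filter = FALSE)
  }
  if (!is.null(signals$pupil)) {
    sig <- interpolate_blinks(signals$pupil)
    feats$pupil <- standardize_feature(
      sig$samples, sig$fs_hz, n_frames, tr_s, name = "pupil", units = "mm (z)")
  }
  if (!is.null(signals$eeg)) {
    fs <- signals$eeg$fs_hz
    feats$alpha_power <- standardize_feature(
      alpha_power(signals$eeg), fs, n_frames, tr_s,
      name = "alpha_power", units = "a.u. (z)")
  }
  feats
}

#' Run the pipeline end to end
#'
#' Executes the toggled stages on a synthetic dataset generated under the
#' configured seed, writing artifacts (NIfTI volumes, BIDS-style physio
#' and events TSVs, feature/curve TSVs, JSON summaries) plus a provenance
#' record per stage when `outdir` is set.
#'
#' @param config Partial configuration; see [default_pipeline_config()].
#' @return Invisible list of in-memory stage results.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- validate_pipeline_config(config)
  lg <- cfg$log_level
  outdir <- cfg$outdir
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  res <- list(config = cfg)
  hash <- config_hash(cfg)
  provenance <- function(stage) {
    if (is.null(outdir)) return(invisible(NULL))
    jsonlite::write_json(
      list(stage = stage, config_hash = hash, seed = cfg$seed,
           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
      file.path(outdir, sprintf("provenance_%s.json", stage)),
      auto_unbox = TRUE)
  }
  run_stage <- function(stage, fun) {
    pipeline_log("info", lg, "stage %s", stage)
    out <- tryCatch(fun(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
    provenance(stage)
    out
  }

  ## simulate ------------------------------------------------------------
  scfg <- do.call(synth_config, c(cfg$synthetic, list(seed = cfg$seed)))
  ds <- run_stage("simulate", function() generate_dataset(scfg))
  res$dataset <- ds
  if (!is.null(outdir)) {
    n <- nrow(ds$fmri$data)
    side <- max(ds$fmri$mask)
    vol <- array(0, c(side, side, side, n))
    for (f in seq_len(n)) {
      v3 <- array(0, c(side, side, side)); v3[ds$fmri$mask] <- ds$fmri$data[f, ]
      vol[, , , f] <- v3
    }
    write_nifti(vol, file.path(outdir, "bold.nii.gz"), tr_s = scfg$tr_s)
    write_physio_bids(lapply(ds$signals, `[[`, "samples"),
                      file.path(outdir, "physio"), scfg$physio_fs_hz)
    write_events_tsv(ds$events, file.path(outdir, "events.tsv"))
    jsonlite::write_json(
      list(voxel_lag_s = ds$truth$voxel_lag_s, voxel_sign = ds$truth$voxel_sign,
           tissue = ds$truth$tissue, beat_times_s = ds$truth$beat_times_s,
           beat_amplitudes = ds$truth$beat_amplitudes, arousal = ds$arousal),
      file.path(outdir, "ground_truth.json"), digits = NA)
  }
  n_frames <- nrow(ds$fmri$data)

  ## physio --------------------------------------------------------------
  if (isTRUE(cfg$stages$physio)) {
    res$features <- run_stage("physio", function() {
      extract_features(ds$signals, n_frames, scfg$tr_s)
    })
    if (!is.null(outdir)) {
      for (nm in names(res$features)) {
        write_feature_tsv(res$features[[nm]],
                          file.path(outdir, sprintf("feature_%s.tsv", nm)))
      }
    }
  }

  ## cpca ----------------------------------------------------------------
  if (isTRUE(cfg$stages$cpca)) {
    res$global <- run_stage("cpca", function() {
      pre <- preprocess_bold(ds$fmri, cfg$cpca$smoothing_fwhm_mm)
      pca <- fit_pca(pre, zscore_runs = cfg$cpca$zscore_runs)
      cpca <- fit_cpca(pre, zscore_runs = cfg$cpca$zscore_runs)
      movie <- reconstruct_movie(cpca, cfg$cpca$n_bins)
      list(pca = pca, cpca = cpca, movie = movie)
    })
    if (!is.null(outdir)) {
      utils::write.table(
        data.frame(frame = seq_along(res$global$pca$scores),
                   pc1 = res$global$pca$scores,
                   cpc1_phase = Arg(res$global$cpca$scores)),
        file.path(outdir, "scores.tsv"), sep = "\t", row.names = FALSE)
      side <- max(ds$fmri$mask)
      ph <- array(0, c(side, side, side))
      ph[ds$fmri$mask] <- res$global$cpca$phase_delay_map
      write_nifti(ph, file.path(outdir, "cpc1_phase.nii.gz"))
      mv <- array(0, c(side, side, side, cfg$cpca$n_bins))
      for (b in seq_len(cfg$cpca$n_bins)) {
        v3 <- array(0, c(side, side, side))
        v3[ds$fmri$mask] <- res$global$movie$maps[b, ]
        mv[, , , b] <- v3
      }
      write_nifti(mv, file.path(outdir, "cpc1_movie.nii.gz"), tr_s = scfg$tr_s)
    }
  }

  pc1_feat <- if (!is.null(res$global)) {
    feature_series(as.numeric(scale(res$global$pca$scores)), scfg$tr_s,
                   name = "global_pc1", units = "z")
  } else {
    NULL
  }

  ## xcorr ---------------------------------------------------------------
  if (isTRUE(cfg$stages$xcorr) && !is.null(pc1_feat) && !is.null(res$features)) {
    res$xcorr <- run_stage("xcorr", function() {
      lapply(res$features, function(f) {
        cross_correlate(pc1_feat, f, cfg$xcorr$max_lag_s)
      })
    })
    if (!is.null(outdir)) {
      for (nm in names(res$xcorr)) {
        write_curve_tsv(res$xcorr[[nm]],
                        file.path(outdir, sprintf("xcorr_%s.tsv", nm)))
      }
    }
  }

  ## irf -----------------------------------------------------------------
  if (isTRUE(cfg$stages$irf) && !is.null(pc1_feat) && !is.null(res$features)) {
    res$irf <- run_stage("irf", function() {
      grid <- seq(cfg$irf$lag_min_s, cfg$irf$lag_max_s, by = scfg$tr_s)
      lapply(res$features, function(f) {
        estimate_irf(pc1_feat, f, grid, length_scale = cfg$irf$length_scale,
                     kernel_variance = cfg$irf$kernel_variance)
      })
    })
    if (!is.null(outdir)) {
      for (nm in names(res$irf)) {
        write_curve_tsv(res$irf[[nm]],
                        file.path(outdir, sprintf("irf_%s.tsv", nm)))
      }
    }
  }

  ## mcca ----------------------------------------------------------------
  if (isTRUE(cfg$stages$mcca)) {
    res$mcca <- run_stage("mcca", function() {
      subject_sets <- lapply(seq_len(cfg$mcca$n_subjects), function(s) {
        sc <- scfg; sc$seed <- (scfg$seed + 1000L * s) %% .Machine$integer.max
        a <- generate_arousal(sc)
        ph <- generate_physio(sc, a)
        fm <- generate_fmri(sc, a)
        feats <- extract_features(ph$signals, length(a), sc$tr_s)
        pre <- preprocess_bold(fm$vts, cfg$cpca$smoothing_fwhm_mm)
        pc1 <- feature_series(as.numeric(scale(fit_pca(pre)$scores)), sc$tr_s,
                              name = "global_pc1")
        feats$global_pc1 <- pc1
        lapply(feats, build_lagged_set, window_s = cfg$mcca$window_s,
               n_splines = cfg$mcca$n_splines)
      })
      permutation_test(subject_sets, n_perm = cfg$mcca$n_perm,
                       seed = cfg$seed, ridge_frac = cfg$mcca$ridge_frac)
    })
    if (!is.null(outdir)) {
      jsonlite::write_json(
        list(pairwise_r = res$mcca$pairwise_r,
             mean_pairwise_r = res$mcca$mean_pairwise_r,
             p_value = res$mcca$p_value, n_perm = res$mcca$n_perm,
             seed = cfg$seed),
        file.path(outdir, "mcca_summary.json"), digits = NA, auto_unbox = TRUE)
    }
  }

  ## events --------------------------------------------------------------
  if (isTRUE(cfg$stages$events) && nrow(ds$events) > 0 && !is.null(pc1_feat)) {
    res$event_avg <- run_stage("events", function() {
      ev <- filter_trials(ds$events, cfg$events$min_gap_s)
      event_average(list(pc1_feat), list(ev), window_s = cfg$events$window_s,
                    n_boot = cfg$events$n_boot, seed = cfg$seed)
    })
    if (!is.null(outdir)) {
      utils::write.table(
        data.frame(time_s = res$event_avg$time_s, mean = res$event_avg$mean,
                   se = res$event_avg$se),
        file.path(outdir, "event_average_pc1.tsv"), sep = "\t",
        row.names = FALSE)
    }
  }

  ## multiecho -----------------------------------------------------------
  if (isTRUE(cfg$stages$multiecho) && !is.null(ds$multiecho)) {
    res$decay <- run_stage("multiecho", function() fit_decay(ds$multiecho))
    if (!is.null(outdir)) {
      utils::write.table(
        data.frame(frame = seq_len(nrow(res$decay$t2s_ms)),
                   median_t2s_ms = apply(res$decay$t2s_ms, 1, stats::median,
                                         na.rm = TRUE),
                   median_s0 = apply(res$decay$s0, 1, stats::median,
                                     na.rm = TRUE)),
        file.path(outdir, "decay_medians.tsv"), sep = "\t", row.names = FALSE)
    }
  }

  if (!is.null(outdir)) {
    jsonlite::write_json(cfg, file.path(outdir, "resolved_config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(res)
}

#' Command-line entry point
#'
#' Subcommands mirror the pipeline stages: `simulate`, `physio`, `cpca`,
#' `xcorr`, `irf`, `mcca`, `events`, `multiecho`, `run-all`. Universal
#' flags: `--seed <int>`, `--config <json>`, `--outdir <dir>`.
#'
#' @param args Character vector of command-line arguments.
#' @return Invisible result of [run_pipeline()].
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste("usage: arousalwave <simulate|physio|cpca|xcorr|irf|mcca|",
                 "events|multiecho|run-all> [--seed N] [--config FILE]",
                 "[--outdir DIR]")
  if (length(args) == 0) stop(usage, call. = FALSE)
  cmd <- args[1]
  stages_all <- c("simulate", "physio", "cpca", "xcorr", "irf", "mcca",
                  "events", "multiecho")
  if (!cmd %in% c(stages_all, "run-all")) stop(usage, call. = FALSE)
  opt <- list(seed = NULL, config = NULL, outdir = NULL)
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opt) || i == length(args)) stop(usage, call. = FALSE)
    opt[[key]] <- args[i + 1]
    i <- i + 2
  }
  config <- if (!is.null(opt$config)) {
    jsonlite::read_json(opt$config, simplifyVector = TRUE)
  } else {
    list()
  }
  if (!is.null(opt$seed)) config$seed <- as.integer(opt$seed)
  if (!is.null(opt$outdir)) config$outdir <- opt$outdir
  if (cmd != "run-all") {
    # cumulative prerequisites: running `xcorr` implies simulate..cpca
    upto <- match(cmd, stages_all)
    need <- stages_all[seq_len(upto)]
    if (cmd %in% c("events", "multiecho")) {
      need <- c("simulate", "physio", "cpca", cmd)
    }
    config$stages <- stats::setNames(as.list(stages_all %in% need), stages_all)
  } else {
    config$stages <- stats::setNames(as.list(rep(TRUE, length(stages_all))),
                                     stages_all)
  }
  invisible(run_pipeline(config))
}
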