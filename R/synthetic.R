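# Synthetic brain-body dataset generator. A single low-frequency latent
# "arousal" process drives (a) voxel time series with a traveling-wave lag
# gradient and tissue-dependent sign (gray/white in phase, CSF anti-phase),
# (b) pulsatile PPG whose beat rate rises and beat amplitude falls with
# arousal, (c) respiration whose rate and depth track arousal, (d) tonic
# skin conductance, pupil and alpha-dominated EEG envelopes, (e) multi-echo
# volumes with arousal-coupled T2*/S0, and (f) sparse cue onsets injecting a
# bimodal evoked response. Ground truth (lags, beat times, carriers) is
# returned so every downstream estimator can be checked by brute force.

#' Synthetic dataset configuration
#'
#' Defaults emulate a desk-scale resting-state acquisition: a 600 s run at
#' TR 1 s, 1000 masked voxels, peripheral recordings at 250 Hz, multi-echo
#' times 13.7/30/47 ms, and coupling lags/signs chosen so PPG amplitude is
#' anticorrelated with arousal while heart rate, respiratory volume, skin
#' conductance, pupil and EEG power are positively coupled.
#'
#' @param duration_s Run length (s); must allow >= 2 cycles at 0.01 Hz.
#' @param tr_s fMRI repetition time (s).
#' @param physio_fs_hz Peripheral/EEG sampling rate (Hz); must be at least
#'   20x the highest carrier frequency (alpha, 10 Hz, with defaults).
#' @param n_voxels Number of masked voxels.
#' @param tissue_fractions Named proportions (`gray`, `white`, `csf`)
#'   summing to 1.
#' @param voxel_lag_range_s Range (min, max) of per-voxel lags (s).
#' @param physio_couplings Per-modality list of `gain` (unitless), `lag_s`
#'   (s, positive = physiological change follows arousal) and `sign`.
#' @param noise_sd Additive voxel noise SD relative to the unit-variance
#'   latent (0.5 = amplitude SNR 2).
#' @param echo_times_ms Echo times (ms), >= 2 values, increasing.
#' @param event_rate Cue rate (events/minute); 0 disables events.
#' @param seed Integer seed fixing all randomness.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(duration_s = 600, tr_s = 1, physio_fs_hz = 250,
                         n_voxels = 1000,
                         tissue_fractions = c(gray = 0.6, white = 0.25, csf = 0.15),
                         voxel_lag_range_s = c(0, 6),
                         physio_couplings = default_couplings(),
                         noise_sd = 0.5,
                         echo_times_ms = c(13.7, 30, 47),
                         event_rate = 0.625,
                         seed = 1L) {
  if (duration_s <= 0 || tr_s <= 0 || physio_fs_hz <= 0) {
    stop("durations, TR and sampling rates must be positive")
  }
  if (physio_fs_hz < 20 * 10) {
    stop("`physio_fs_hz` must be >= 20x the highest carrier frequency (10 Hz alpha)")
  }
  if (any(tissue_fractions < 0) || abs(sum(tissue_fractions) - 1) > 1e-8) {
    stop("`tissue_fractions` must be nonnegative and sum to 1")
  }
  if (length(voxel_lag_range_s) != 2 || diff(voxel_lag_range_s) < 0) {
    stop("`voxel_lag_range_s` must be c(min, max) with min <= max")
  }
  cfg <- list(duration_s = duration_s, tr_s = tr_s, physio_fs_hz = physio_fs_hz,
              n_voxels = as.integer(n_voxels),
              tissue_fractions = tissue_fractions,
              voxel_lag_range_s = voxel_lag_range_s,
              physio_couplings = physio_couplings, noise_sd = noise_sd,
              echo_times_ms = echo_times_ms, event_rate = event_rate,
              seed = as.integer(seed))
  class(cfg) <- "synth_config"
  cfg
}

#' Default arousal-to-physiology couplings
#'
#' Gains are free parameters of the generator (the study they emulate
#' reports correlation magnitudes, not gains); the defaults give extracted
#' feature-to-arousal correlations of roughly 0.2-0.4 at the default noise
#' level. Signs and lags follow the physiology: PPG amplitude falls
#' (vasoconstriction) ~2 s after arousal; heart rate, respiratory volume,
#' skin conductance, pupil and EEG power rise.
#' @return Named list of per-modality coupling parameters.
#' @export
default_couplings <- function() {
  list(heart_rate       = list(gain = 0.10, lag_s = 1.0, sign = 1),
       ppg_amplitude    = list(gain = 0.40, lag_s = 2.0, sign = -1),
       respiration      = list(gain = 0.30, lag_s = 0.5, sign = 1),
       skin_conductance = list(gain = 1.00, lag_s = 4.0, sign = 1),
       pupil            = list(gain = 1.00, lag_s = 0.5, sign = 1),
       eeg              = list(gain = 0.50, lag_s = 0.0, sign = 1))
}

# deterministic per-stage seed streams so toggling one stage never perturbs
# another's randomness
stage_seed <- function(cfg, stage) {
  offsets <- c(arousal = 0L, physio = 101L, fmri = 211L, multiecho = 307L,
               events = 401L)
  (cfg$seed + offsets[[stage]]) %% .Machine$integer.max
}

#' Generate the latent arousal process
#'
#' White Gaussian noise on the fMRI frame grid, passed through the same
#' fifth-order zero-phase 0.01-0.1 Hz Butterworth bandpass used in
#' preprocessing, then standardized to zero mean and unit SD exactly.
#'
#' @param cfg A [synth_config()].
#' @return Numeric vector of length `duration_s / tr_s` (frames).
#' @export
generate_arousal <- function(cfg) {
  if (cfg$duration_s < 2 / 0.01) {
    stop("`duration_s` too short to resolve 0.01 Hz (need >= 2 cycles, i.e. 200 s)")
  }
  n <- round(cfg$duration_s / cfg$tr_s)
  set.seed(stage_seed(cfg, "arousal"))
  x <- stats::rnorm(n)
  x <- bandpass_filter(x, 1 / cfg$tr_s)
  as.numeric(scale(x))
}

# evaluate the latent, shifted by `lag_s` and resampled to an arbitrary
# time grid (edge-held, never circular)
lagged_latent <- function(arousal, tr_s, t_query, lag_s) {
  n <- length(arousal)
  f <- stats::splinefun(seq(0, n - 1) * tr_s, arousal, method = "fmm")
  f(pmin(pmax(t_query - lag_s, 0), (n - 1) * tr_s))
}

# fixed PPG pulse template on beat phase u in [0, 1): a sharp systolic bump
# and a smaller dicrotic bump
ppg_pulse_template <- function(u) {
  exp(-((u - 0.15) / 0.07)^2) + 0.35 * exp(-((u - 0.45) / 0.12)^2)
}

#' Generate raw peripheral and EEG recordings coupled to the latent
#'
#' @param cfg A [synth_config()].
#' @param arousal Latent series from [generate_arousal()].
#' @return List with `signals` (named list of [raw_physio_signal()]s) and
#'   `truth` (beat times/amplitudes, per-sample breathing rate and depth,
#'   coupling table, per-modality true lag/sign/gain).
#' @export
generate_physio <- function(cfg, arousal) {
  if (stats::sd(arousal) == 0) stop("degenerate arousal input (zero variance)")
  set.seed(stage_seed(cfg, "physio"))
  fs <- cfg$physio_fs_hz
  n_s <- round(cfg$duration_s * fs)
  t <- seq(0, n_s - 1) / fs
  cp <- cfg$physio_couplings

  ## --- PPG: integrate instantaneous heart rate to place beats ----------
  hr_lat <- lagged_latent(arousal, cfg$tr_s, t, cp$heart_rate$lag_s)
  hr_bpm <- 60 * (1 + cp$heart_rate$gain * cp$heart_rate$sign * hr_lat)
  hr_bpm <- pmax(hr_bpm, 30)
  phase <- cumsum(hr_bpm / 60) / fs        # beats elapsed; cycle k = [k-1, k)
  n_beats <- floor(phase[n_s])
  # true systole times: the pulse template peaks 0.15 cycles into each beat
  beat_times <- stats::approx(phase, t, xout = seq_len(n_beats) - 1 + 0.15)$y
  amp_lat <- lagged_latent(arousal, cfg$tr_s, beat_times, cp$ppg_amplitude$lag_s)
  # multiplicative (log-linear) modulation: vascular tone scales, and never
  # zeroes, the pulse amplitude
  beat_amp <- exp(cp$ppg_amplitude$gain * cp$ppg_amplitude$sign * amp_lat) *
    (1 + stats::rnorm(n_beats, sd = 0.03))
  beat_idx <- pmin(floor(phase) + 1, n_beats)
  ppg <- beat_amp[beat_idx] * ppg_pulse_template(phase - floor(phase)) +
    stats::rnorm(n_s, sd = 0.01)

  ## --- respiration: rate and depth track lagged arousal ----------------
  rs_lat <- lagged_latent(arousal, cfg$tr_s, t, cp$respiration$lag_s)
  br_hz <- 0.25 * exp(cp$respiration$gain * cp$respiration$sign * rs_lat)
  depth <- exp(cp$respiration$gain * cp$respiration$sign * rs_lat)
  resp <- depth * sin(2 * pi * cumsum(br_hz) / fs) + stats::rnorm(n_s, sd = 0.02)

  ## --- tonic skin conductance and pupil: lagged smoothed copies --------
  sc <- 5 + cp$skin_conductance$gain * cp$skin_conductance$sign *
    lagged_latent(arousal, cfg$tr_s, t, cp$skin_conductance$lag_s) +
    lowpass_filter(stats::rnorm(n_s, sd = 3), fs, 0.1, order = 4)
  pupil <- 4 + cp$pupil$gain * cp$pupil$sign *
    lagged_latent(arousal, cfg$tr_s, t, cp$pupil$lag_s) +
    lowpass_filter(stats::rnorm(n_s, sd = 3), fs, 0.2, order = 4)

  ## --- EEG: alpha-dominated oscillation, envelope tracks arousal -------
  env <- pmax(1 + cp$eeg$gain * cp$eeg$sign *
                lagged_latent(arousal, cfg$tr_s, t, cp$eeg$lag_s), 0.05)
  broadband <- bandpass_filter(stats::rnorm(n_s), fs, 2, 12, order = 3)
  broadband <- broadband / stats::sd(broadband)
  eeg <- env * (0.7 * sin(2 * pi * 10 * t + stats::runif(1, 0, 2 * pi)) +
                  0.5 * broadband) + stats::rnorm(n_s, sd = 0.05)

  signals <- list(
    ppg = raw_physio_signal(ppg, fs, "ppg"),
    respiration = raw_physio_signal(resp, fs, "respiration"),
    skin_conductance = raw_physio_signal(sc, fs, "skin_conductance"),
    pupil = raw_physio_signal(pupil, fs, "pupil"),
    eeg = raw_physio_signal(eeg, fs, "eeg_channel"))
  truth <- list(beat_times_s = beat_times, beat_amplitudes = beat_amp,
                breath_rate_hz = br_hz, breath_depth = depth,
                couplings = cp)
  list(signals = signals, truth = truth)
}

#' Generate voxel time series with a traveling-wave lag gradient
#'
#' Each voxel is a sign-flipped, lag-shifted copy of the latent plus iid
#' Gaussian noise. Gray and white voxels carry sign +1, CSF voxels -1
#' (anti-phase), and per-voxel lags are drawn uniformly from the configured
#' range. A small 3D lattice mask is attached so NIfTI round trips are
#' exercised.
#'
#' @param cfg A [synth_config()].
#' @param arousal Latent series on the fMRI grid.
#' @return List with `vts` (a [voxel_time_series()]) and `truth`
#'   (`voxel_lag_s`, `voxel_sign`, `tissue`).
#' @export
generate_fmri <- function(cfg, arousal) {
  set.seed(stage_seed(cfg, "fmri"))
  n <- length(arousal)
  nv <- cfg$n_voxels
  counts <- round(nv * cfg$tissue_fractions)
  counts[1] <- nv - sum(counts[-1])
  tissue <- rep(names(cfg$tissue_fractions), counts)
  sign_v <- ifelse(tissue == "csf", -1, 1)
  lag_v <- stats::runif(nv, cfg$voxel_lag_range_s[1], cfg$voxel_lag_range_s[2])
  f <- stats::splinefun(seq(0, n - 1) * cfg$tr_s, arousal, method = "fmm")
  t_grid <- seq(0, n - 1) * cfg$tr_s
  data <- matrix(0, n, nv)
  for (v in seq_len(nv)) {
    tq <- pmin(pmax(t_grid - lag_v[v], 0), t_grid[n])
    data[, v] <- sign_v[v] * f(tq)
  }
  if (cfg$noise_sd > 0) {
    data <- data + matrix(stats::rnorm(n * nv, sd = cfg$noise_sd), n, nv)
  }
  side <- ceiling(nv^(1 / 3))
  coords <- as.matrix(expand.grid(x = seq_len(side), y = seq_len(side),
                                  z = seq_len(side)))[seq_len(nv), , drop = FALSE]
  vts <- voxel_time_series(data, cfg$tr_s, mask = coords, tissue_label = tissue)
  list(vts = vts, truth = list(voxel_lag_s = lag_v, voxel_sign = sign_v,
                               tissue = tissue))
}

#' Generate multi-echo volumes with arousal-coupled T2* and S0
#'
#' Signal at echo time TE is `S0(t) * exp(-TE / T2*(t))` with per-tissue
#' baselines (gray 45 ms, white 50 ms, CSF 150 ms; S0 = 1000) and opposing
#' arousal modulation of T2* and S0, mirroring blood-volume-like effects.
#'
#' @param cfg A [synth_config()] (needs >= 2 positive echo times).
#' @param arousal Latent series on the fMRI grid.
#' @param n_voxels Voxel count for the multi-echo grid (defaults to a
#'   quarter of `cfg$n_voxels`; these fits are per frame/voxel, so small
#'   grids keep runtimes sensible).
#' @return List with `me` (a `multi_echo_series`: `data` frames x echoes x
#'   voxels, `echo_times_ms`, `tr_s`, `slice_of_voxel`) and `truth`
#'   (`t2s_series_ms`, `s0_series`, frames x voxels).
#' @export
generate_multiecho <- function(cfg, arousal, n_voxels = NULL) {
  if (length(cfg$echo_times_ms) < 2) stop("need at least 2 echo times")
  if (any(cfg$echo_times_ms <= 0)) stop("echo times must be positive")
  set.seed(stage_seed(cfg, "multiecho"))
  if (is.null(n_voxels)) n_voxels <- max(4L, cfg$n_voxels %/% 4L)
  n <- length(arousal)
  counts <- round(n_voxels * cfg$tissue_fractions)
  counts[1] <- n_voxels - sum(counts[-1])
  tissue <- rep(names(cfg$tissue_fractions), counts)
  base_t2s <- c(gray = 45, white = 50, csf = 150)[tissue]
  sign_v <- ifelse(tissue == "csf", -1, 1)
  lag_v <- stats::runif(n_voxels, cfg$voxel_lag_range_s[1], cfg$voxel_lag_range_s[2])
  f <- stats::splinefun(seq(0, n - 1) * cfg$tr_s, arousal, method = "fmm")
  t_grid <- seq(0, n - 1) * cfg$tr_s
  lat <- vapply(seq_len(n_voxels), function(v) {
    f(pmin(pmax(t_grid - lag_v[v], 0), t_grid[n]))
  }, numeric(n))
  t2s <- sweep(1 + 0.05 * sweep(lat, 2, sign_v, `*`), 2, base_t2s, `*`)
  s0 <- 1000 * (1 - 0.03 * sweep(lat, 2, sign_v, `*`))
  ne <- length(cfg$echo_times_ms)
  data <- array(0, dim = c(n, ne, n_voxels))
  for (e in seq_len(ne)) {
    clean <- s0 * exp(-cfg$echo_times_ms[e] / t2s)
    data[, e, ] <- clean * exp(stats::rnorm(n * n_voxels, sd = cfg$noise_sd * 0.01))
  }
  me <- structure(list(data = data, echo_times_ms = cfg$echo_times_ms,
                       tr_s = cfg$tr_s,
                       slice_of_voxel = ((seq_len(n_voxels) - 1) %% 4) + 1,
                       tissue_label = tissue),
                  class = "multi_echo_series")
  list(me = me, truth = list(t2s_series_ms = t2s, s0_series = s0,
                             voxel_lag_s = lag_v, voxel_sign = sign_v,
                             tissue = tissue))
}

#' Bimodal evoked arousal waveform
#'
#' Early positive peak (~4 s) followed by a stronger, more prolonged
#' undershoot (trough ~14 s), the response shape elicited by cued deep
#' breaths and phasic arousal events.
#'
#' @param t_s Time since onset (s).
#' @param peak_amp,undershoot_amp Peak/undershoot magnitudes (z units).
#' @return Waveform values at `t_s`.
#' @export
evoked_waveform <- function(t_s, peak_amp = 1, undershoot_amp = 1.5) {
  g <- function(t, k, th) {
    d <- stats::dgamma(t, shape = k, scale = th)
    d / stats::dgamma((k - 1) * th, shape = k, scale = th)
  }
  out <- peak_amp * g(t_s, 5, 1) - undershoot_amp * g(t_s, 8, 2)
  out[t_s < 0] <- 0
  out
}

#' Generate sparse cue onsets with jittered inter-stimulus intervals
#'
#' Inter-onset intervals are drawn uniformly from `mean_isi * (1 +/-
#' jitter_frac)` where `mean_isi = 60 / event_rate`; the defaults emulate a
#' sparse auditory-cue design with ISIs of roughly 60-131 s.
#'
#' @param cfg A [synth_config()].
#' @param jitter_frac Fractional ISI jitter (default 0.369).
#' @param response_rate Probability a trial has a button response.
#' @return Data frame with `onset`, `duration`, `trial_type`, `response`.
#' @export
generate_events <- function(cfg, jitter_frac = 0.369, response_rate = 0.9) {
  set.seed(stage_seed(cfg, "events"))
  if (cfg$event_rate <= 0) {
    return(data.frame(onset = numeric(0), duration = numeric(0),
                      trial_type = character(0), response = logical(0)))
  }
  mean_isi <- 60 / cfg$event_rate
  onsets <- c()
  t <- stats::runif(1, 5, mean_isi)
  while (t < cfg$duration_s - 30) {
    onsets <- c(onsets, t)
    t <- t + stats::runif(1, mean_isi * (1 - jitter_frac),
                          mean_isi * (1 + jitter_frac))
  }
  data.frame(onset = onsets, duration = 0,
             trial_type = "cue",
             response = stats::runif(length(onsets)) < response_rate)
}

#' Inject the evoked waveform into a frame-grid series at event onsets
#'
#' @param x Series on the fMRI frame grid (e.g. the latent arousal).
#' @param onsets_s Event onsets (s).
#' @param tr_s Repetition time (s).
#' @param window_s Support of the evoked response (s).
#' @param ... Passed to [evoked_waveform()].
#' @return `x` with the waveform added at each onset.
#' @export
inject_events <- function(x, onsets_s, tr_s, window_s = 30, ...) {
  n <- length(x)
  t <- seq(0, n - 1) * tr_s
  for (on in onsets_s) {
    idx <- which(t >= on & t <= on + window_s)
    x[idx] <- x[idx] + evoked_waveform(t[idx] - on, ...)
  }
  x
}

#' Generate a complete coupled dataset
#'
#' Runs all generators under the configured seed: latent arousal (with
#' evoked responses injected when `event_rate > 0`), peripheral/EEG
#' recordings, single-echo voxel data, multi-echo volumes and the event
#' table.
#'
#' @param cfg A [synth_config()].
#' @param with_multiecho Generate the multi-echo block (default TRUE).
#' @return List: `arousal`, `signals`, `fmri`, `multiecho`, `events`,
#'   `truth` (merged ground truth), `cfg`.
#' @export
generate_dataset <- function(cfg, with_multiecho = TRUE) {
  arousal <- generate_arousal(cfg)
  events <- generate_events(cfg)
  if (nrow(events) > 0) {
    arousal <- inject_events(arousal, events$onset, cfg$tr_s)
  }
  phys <- generate_physio(cfg, arousal)
  fmri <- generate_fmri(cfg, arousal)
  me <- if (with_multiecho) generate_multiecho(cfg, arousal) else NULL
  truth <- c(list(arousal = arousal), phys$truth, fmri$truth,
             list(multiecho = if (is.null(me)) NULL else me$truth,
                  evoked = function(t) evoked_waveform(t)))
  list(arousal = arousal, signals = phys$signals, fmri = fmri$vts,
       multiecho = if (is.null(me)) NULL else me$me,
       events = events, truth = truth, cfg = cfg)
}
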