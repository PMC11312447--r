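# Event-related averaging around cue/arousal onsets: trial filtering by
# minimum separation and response, peri-event averaging on a common grid,
# cluster-bootstrap (subject-level) standard errors, and baseline-dB
# normalized EEG power averages.

#' Filter trials by separation and response
#'
#' A trial is removed when its gap to the previous OR next onset is below
#' `min_gap_s` (both members of a close pair go), avoiding overlapping
#' responses; optionally, non-response trials are removed first.
#'
#' @param events Data frame with `onset` (sorted ascending) and optionally
#'   `response`.
#' @param min_gap_s Minimum inter-onset separation (s), default 30.
#' @param require_response Drop trials with `response == FALSE`.
#' @return The filtered events data frame (possibly empty).
#' @export
filter_trials <- function(events, min_gap_s = 30, require_response = FALSE) {
  ev <- as.data.frame(events)
  if (nrow(ev) == 0) return(ev)
  if (is.unsorted(ev$onset)) stop("`onset` must be sorted ascending")
  if (require_response) {
    if (is.null(ev$response)) stop("`response` column required")
    ev <- ev[as.logical(ev$response), , drop = FALSE]
  }
  if (nrow(ev) <= 1) return(ev)
  gaps <- diff(ev$onset)
  bad <- c(gaps < min_gap_s, FALSE) | c(FALSE, gaps < min_gap_s)
  ev[!bad, , drop = FALSE]
}

#' Peri-event average of frame-grid series across trials and subjects
#'
#' Each run is z-scored in time, each trial's segment is linearly
#' interpolated onto a common peri-event grid (step = TR, 0 to
#' `window_s`), and the grand mean over trials is reported together with a
#' cluster-bootstrap standard error (subjects resampled with
#' replacement).
#'
#' @param runs Named-by-subject list of [feature_series()] (or numeric
#'   vectors sharing `tr_s`).
#' @param events_by_subject List (same order) of event data frames with
#'   `onset` in seconds.
#' @param window_s Peri-event window length (s), default 29.
#' @param tr_s Frame step; from the first run when omitted.
#' @param n_boot Bootstrap replicates for the SE (default 500).
#' @param zscore Z-score each run before extraction (default TRUE).
#' @param seed RNG seed for the bootstrap.
#' @return An `event_average`: `time_s`, `mean`, `se`, `n_trials`,
#'   `n_subjects`, `n_dropped` (trials exceeding the run end).
#' @export
event_average <- function(runs, events_by_subject, window_s = 29, tr_s = NULL,
                          n_boot = 500, zscore = TRUE, seed = 1) {
  if (length(runs) != length(events_by_subject)) {
    stop("`runs` and `events_by_subject` must have equal length")
  }
  if (is.null(tr_s)) {
    tr_s <- if (inherits(runs[[1]], "feature_series")) runs[[1]]$tr_s else 1
  }
  grid <- seq(0, window_s, by = tr_s)
  subj_trials <- list()
  n_dropped <- 0
  for (s in seq_along(runs)) {
    x <- if (inherits(runs[[s]], "feature_series")) runs[[s]]$values else
      as.numeric(runs[[s]])
    if (zscore) x <- as.numeric(scale(x))
    t_run <- seq(0, length(x) - 1) * tr_s
    segs <- list()
    for (on in events_by_subject[[s]]$onset) {
      if (on + window_s > t_run[length(t_run)]) {
        n_dropped <- n_dropped + 1
        next
      }
      segs[[length(segs) + 1]] <- stats::approx(t_run, x, xout = on + grid)$y
    }
    if (length(segs) > 0) {
      subj_trials[[length(subj_trials) + 1]] <- do.call(rbind, segs)
    }
  }
  if (n_dropped > 0) {
    warning(sprintf("%d trial(s) dropped: window exceeded the run end", n_dropped))
  }
  if (length(subj_trials) == 0) stop("no usable trials")
  all_trials <- do.call(rbind, subj_trials)
  subj_means <- do.call(rbind, lapply(subj_trials, colMeans))
  se <- if (nrow(subj_means) >= 2) {
    cluster_bootstrap_se(subj_means, n_boot = n_boot, seed = seed)
  } else {
    rep(NA_real_, length(grid))
  }
  structure(list(time_s = grid, mean = colMeans(all_trials), se = se,
                 n_trials = nrow(all_trials), n_subjects = length(subj_trials),
                 n_dropped = n_dropped),
            class = "event_average")
}

#' Cluster-bootstrap standard error of a group mean
#'
#' Resamples subjects with replacement, recomputes the group mean of the
#' per-subject means, and reports the SD over replicates pointwise.
#'
#' @param subject_means Subjects x grid matrix of per-subject trial means.
#' @param n_boot Number of bootstrap replicates (default 500).
#' @param seed RNG seed.
#' @return Numeric SE series (length = grid).
#' @export
cluster_bootstrap_se <- function(subject_means, n_boot = 500, seed = 1) {
  subject_means <- as.matrix(subject_means)
  ns <- nrow(subject_means)
  if (ns < 2) stop("cluster bootstrap needs at least 2 subjects")
  set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(i) {
    colMeans(subject_means[sample(ns, replace = TRUE), , drop = FALSE])
  }, numeric(ncol(subject_means)))
  apply(matrix(reps, ncol = n_boot), 1, stats::sd)
}

#' Event-related EEG power in decibels
#'
#' Per subject: average the time-frequency power over trials, then apply
#' baseline log-ratio normalization `10 * log10(P(t, f) / Pbar_base(f))`
#' with the mean over `baseline_s` (default 1 s before onset up to onset)
#' as baseline; finally average across subjects.
#'
#' @param trials_by_subject List over subjects; each element a list of
#'   per-trial time x frequency matrices on a common peri-event grid.
#' @param time_s Peri-event time grid (s; negative = pre-onset) matching
#'   the matrices' rows.
#' @param baseline_s Baseline window `(start, end)` relative to onset,
#'   default `c(-1, 0)`.
#' @param window_s Post-onset extent reported (default 20).
#' @return List: `time_s`, `freqs` (column names if present), `db`
#'   (time x frequency group average, dB), `n_subjects`.
#' @export
eeg_event_power <- function(trials_by_subject, time_s, baseline_s = c(-1, 0),
                            window_s = 20) {
  base_idx <- which(time_s >= baseline_s[1] & time_s <= baseline_s[2])
  if (length(base_idx) == 0) {
    stop("no pre-onset samples available for the baseline window")
  }
  keep_idx <- which(time_s >= baseline_s[1] & time_s <= window_s)
  subj_db <- lapply(trials_by_subject, function(trials) {
    avg <- Reduce(`+`, trials) / length(trials)
    base <- colMeans(avg[base_idx, , drop = FALSE])
    10 * log10(sweep(avg, 2, base, `/`))[keep_idx, , drop = FALSE]
  })
  db <- Reduce(`+`, subj_db) / length(subj_db)
  list(time_s = time_s[keep_idx],
       freqs = colnames(trials_by_subject[[1]][[1]]),
       db = db, n_subjects = length(trials_by_subject))
}

#' @export
print.event_average <- function(x, ...) {
  cat(sprintf("<event_average> %d trials, %d subjects, window 0-%.3g s\n",
              x$n_trials, x$n_subjects, max(x$time_s)))
  invisible(x)
}
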