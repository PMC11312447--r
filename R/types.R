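# Lightweight S3 containers for the objects that move between pipeline
# stages. Constructors validate the invariants each downstream stage
# assumes.

#' Construct a raw physiological signal
#'
#' A uniformly sampled recording from one peripheral or EEG channel.
#'
#' @param samples Numeric vector in native units. Missing values are only
#'   permitted for pupil recordings (blinks).
#' @param fs_hz Sampling frequency (Hz), positive.
#' @param modality One of `"ppg"`, `"respiration"`, `"skin_conductance"`,
#'   `"pupil"`, `"eeg_channel"`.
#' @param start_time_s Onset relative to the first fMRI volume (s).
#' @return A `raw_physio_signal` object.
#' @export
raw_physio_signal <- function(samples, fs_hz, modality, start_time_s = 0) {
  modality <- match.arg(modality,
    c("ppg", "respiration", "skin_conductance", "pupil", "eeg_channel"))
  if (fs_hz <= 0) stop("`fs_hz` must be positive")
  if (modality != "pupil" && any(!is.finite(samples))) {
    stop("non-finite samples are only permitted for pupil recordings")
  }
  structure(list(samples = as.numeric(samples), fs_hz = fs_hz,
                 modality = modality, start_time_s = start_time_s),
            class = "raw_physio_signal")
}

#' Construct a beat series (detected systolic peaks)
#'
#' @param peak_times_s Strictly increasing peak times (s).
#' @param peak_amplitudes Peak heights in the units of the filtered PPG.
#' @return A `beat_series` object.
#' @export
beat_series <- function(peak_times_s, peak_amplitudes) {
  if (length(peak_times_s) != length(peak_amplitudes)) {
    stop("times and amplitudes must have equal length")
  }
  if (length(peak_times_s) > 1 && any(diff(peak_times_s) <= 0)) {
    stop("`peak_times_s` must be strictly increasing")
  }
  if (any(!is.finite(peak_amplitudes))) stop("amplitudes must be finite")
  structure(list(peak_times_s = as.numeric(peak_times_s),
                 peak_amplitudes = as.numeric(peak_amplitudes)),
            class = "beat_series")
}

#' Construct a feature series on the fMRI frame grid
#'
#' @param values Per-frame values.
#' @param tr_s Repetition time (s).
#' @param name Feature label (e.g. `"heart_rate"`).
#' @param units Unit label.
#' @return A `feature_series` object.
#' @export
feature_series <- function(values, tr_s, name = "feature", units = "a.u.") {
  if (tr_s <= 0) stop("`tr_s` must be positive")
  structure(list(values = as.numeric(values), tr_s = tr_s, name = name,
                 units = units), class = "feature_series")
}

#' Construct a voxel time-series container
#'
#' @param data Frames x voxels numeric matrix.
#' @param tr_s Repetition time (s).
#' @param mask Integer matrix (voxels x 3) of lattice coordinates, or NULL.
#' @param tissue_label Optional per-voxel factor/character
#'   (`gray`/`white`/`csf`/`vein`/`other`).
#' @param subject_id Label.
#' @return A `voxel_time_series` object.
#' @export
voxel_time_series <- function(data, tr_s, mask = NULL, tissue_label = NULL,
                              subject_id = "sub-01") {
  data <- as.matrix(data)
  if (any(!is.finite(data))) stop("`data` must be finite")
  if (!is.null(tissue_label) && length(tissue_label) != ncol(data)) {
    stop("`tissue_label` length must equal the voxel count")
  }
  if (!is.null(mask) && nrow(mask) != ncol(data)) {
    stop("`mask` must have one row per voxel")
  }
  structure(list(data = data, tr_s = tr_s, mask = mask,
                 tissue_label = tissue_label, subject_id = subject_id),
            class = "voxel_time_series")
}

#' @export
print.voxel_time_series <- function(x, ...) {
  cat(sprintf("<voxel_time_series> %d frames x %d voxels, TR %.3g s, subject %s\n",
              nrow(x$data), ncol(x$data), x$tr_s, x$subject_id))
  invisible(x)
}

#' @export
print.feature_series <- function(x, ...) {
  cat(sprintf("<feature_series> %s [%s], %d frames, TR %.3g s\n",
              x$name, x$units, length(x$values), x$tr_s))
  invisible(x)
}
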