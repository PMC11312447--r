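# Feature extraction from raw peripheral and EEG recordings: systolic peak
# detection (two-moving-average scheme), heart rate and PPG amplitude by
# monotone cubic interpolation, Hilbert-based respiratory volume, tonic
# skin conductance, Morlet wavelet EEG power, alpha envelope, and the
# common clip -> resample -> bandpass standardization onto the fMRI grid.

moving_average <- function(x, w) {
  w <- max(1L, as.integer(w))
  k <- rep(1 / w, w)
  n <- length(x)
  xe <- c(rep(x[1], w), x, rep(x[n], w))
  y <- stats::filter(xe, k, method = "convolution", sides = 2)
  as.numeric(y)[(w + 1):(w + n)]
}

#' Detect systolic peaks in a PPG recording
#'
#' Bandpasses the signal (third-order Butterworth, 0.5-8 Hz), then applies
#' the two-moving-average event-detection scheme: the clipped, squared
#' signal is smoothed with a short "peak" window and a longer "beat"
#' window; blocks where the peak average exceeds the beat average plus an
#' offset are candidate systoles, and the maximum of the filtered signal
#' within each sufficiently wide block is the peak.
#'
#' @param sig A [raw_physio_signal()] with modality `"ppg"`.
#' @param w1_s Peak moving-average window (s), default 0.111.
#' @param w2_s Beat moving-average window (s), default 0.667.
#' @param beta Threshold offset as a fraction of the mean squared signal,
#'   default 0.02.
#' @return A [beat_series()] of peak times and amplitudes (amplitudes read
#'   from the bandpassed signal).
#' @export
detect_ppg_peaks <- function(sig, w1_s = 0.111, w2_s = 0.667, beta = 0.02) {
  stopifnot(inherits(sig, "raw_physio_signal"))
  if (sig$modality != "ppg") stop("`sig` must have modality 'ppg'")
  fs <- sig$fs_hz
  if (length(sig$samples) / fs < 5) stop("PPG record must be at least 5 s long")
  if (stats::sd(sig$samples) < 1e-12) stop("no peaks detected: flat PPG signal")
  x <- bandpass_filter(sig$samples, fs, 0.5, 8, order = 3)
  sq <- pmax(x, 0)^2
  ma_peak <- moving_average(sq, round(w1_s * fs))
  ma_beat <- moving_average(sq, round(w2_s * fs))
  thr <- ma_beat + beta * mean(sq)
  block <- ma_peak > thr
  if (!any(block)) stop("no peaks detected in PPG signal")
  r <- rle(block)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= round(w1_s * fs)
  peaks <- integer(0)
  for (i in which(keep)) {
    seg <- starts[i]:ends[i]
    peaks <- c(peaks, seg[which.max(x[seg])])
  }
  if (length(peaks) == 0) stop("no peaks detected in PPG signal")
  beat_series((peaks - 1) / fs + sig$start_time_s, x[peaks])
}

beat_interp <- function(times, values, fs_hz, n_samples, start_time_s = 0) {
  if (length(times) < 2) stop("need at least 2 beats to interpolate")
  f <- stats::splinefun(times, values, method = "monoH.FC")
  t <- seq(0, n_samples - 1) / fs_hz + start_time_s
  f(pmin(pmax(t, times[1]), times[length(times)]))
}

#' Instantaneous heart rate from detected beats
#'
#' The rate 60/IBI (bpm) is assigned at each beat (at the second beat of
#' each interval) and interpolated to the raw-signal grid with monotone
#' cubic interpolation; values beyond the first/last beat hold the
#' boundary value.
#'
#' @param beats A [beat_series()].
#' @param fs_hz Target grid sampling frequency (Hz).
#' @param n_samples Target grid length.
#' @param start_time_s Grid onset (s).
#' @return Numeric heart-rate series (bpm) of length `n_samples`.
#' @export
heart_rate <- function(beats, fs_hz, n_samples, start_time_s = 0) {
  tb <- beats$peak_times_s
  if (length(tb) < 2) stop("need at least 2 beats to compute heart rate")
  ibi <- diff(tb)
  beat_interp(tb[-1], 60 / ibi, fs_hz, n_samples, start_time_s)
}

#' PPG amplitude series from detected beats
#'
#' Systolic peak amplitudes interpolated to the raw-signal grid with
#' monotone cubic interpolation (boundary values held outside the beat
#' span).
#'
#' @inheritParams heart_rate
#' @return Numeric amplitude series of length `n_samples`.
#' @export
ppg_amplitude <- function(beats, fs_hz, n_samples, start_time_s = 0) {
  if (length(beats$peak_times_s) < 2) stop("need at least 2 beats")
  beat_interp(beats$peak_times_s, beats$peak_amplitudes, fs_hz, n_samples,
              start_time_s)
}

#' Respiratory volume from a respiration-belt recording
#'
#' Tenth-order Butterworth lowpass (< 0.75 Hz), analytic signal, then an
#' iterated linear-interpolation correction of the unwrapped phase: samples
#' on decreasing phase segments are replaced by linear interpolation
#' between surrounding non-decreasing samples until the phase is
#' non-decreasing. Respiratory volume is the phase derivative
#' (instantaneous breathing rate, rad/s) times the amplitude envelope
#' (breathing depth).
#'
#' @param sig A [raw_physio_signal()] with modality `"respiration"`.
#' @param max_iter Iteration cap for the phase monotonization.
#' @return Numeric RV series on the raw-signal grid.
#' @export
respiratory_volume <- function(sig, max_iter = 50) {
  stopifnot(inherits(sig, "raw_physio_signal"))
  if (sig$modality != "respiration") stop("`sig` must have modality 'respiration'")
  x <- sig$samples
  if (stats::sd(x) < 1e-12) stop("degenerate respiration signal (zero variance)")
  fs <- sig$fs_hz
  xf <- lowpass_filter(x - mean(x), fs, 0.75, order = 10)
  a <- analytic_signal(xf)
  amp <- Mod(a)
  ph <- unwrap_phase(Arg(a))
  it <- 0
  while (any(diff(ph) < 0)) {
    it <- it + 1
    if (it > max_iter) {
      stop(sprintf("phase monotonization did not converge in %d iterations (%d decreasing samples remain)",
                   max_iter, sum(diff(ph) < 0)))
    }
    # remove both ends of each decreasing step (the spurious local maximum
    # and the dip after it) so phase slips resolve quickly
    dec <- which(diff(ph) < 0)
    bad <- rep(FALSE, length(ph))
    bad[dec] <- TRUE
    bad[dec + 1] <- TRUE
    good <- which(!bad)
    if (length(good) < 2) stop("phase monotonization removed all samples")
    ph <- stats::approx(good, ph[good], xout = seq_along(ph), rule = 2)$y
  }
  dph <- c(diff(ph), ph[length(ph)] - ph[length(ph) - 1]) * fs
  dph * amp
}

unwrap_phase <- function(p) {
  dp <- diff(p)
  jumps <- cumsum(c(0, -2 * pi * round(dp / (2 * pi))))
  p + jumps
}

#' Tonic skin conductance
#'
#' Zero-phase fifth-order Butterworth bandpass (0.01-0.1 Hz) isolating the
#' slowly varying sudomotor component.
#'
#' @param sig A [raw_physio_signal()] with modality `"skin_conductance"`.
#' @return Filtered series on the raw-signal grid.
#' @export
tonic_skin_conductance <- function(sig) {
  stopifnot(inherits(sig, "raw_physio_signal"))
  if (sig$modality != "skin_conductance") {
    stop("`sig` must have modality 'skin_conductance'")
  }
  if (length(sig$samples) / sig$fs_hz < 2 / 0.01) {
    stop("recording shorter than 2 cycles at 0.01 Hz (200 s)")
  }
  bandpass_filter(sig$samples, sig$fs_hz)
}

#' Morlet wavelet time-frequency EEG power
#'
#' Convolves the channel with a bank of complex Morlet wavelets (default
#' 15 cycles per wavelet, frequencies spanning 2-20 Hz) and returns the
#' squared magnitude: instantaneous power per time sample and frequency.
#'
#' @param sig A [raw_physio_signal()] with modality `"eeg_channel"`.
#' @param freqs_hz Frequency grid (Hz); default `seq(2, 20, by = 1)`.
#' @param n_cycles Wavelet cycles (default 15).
#' @return Matrix, time x frequency, with `freqs_hz` as column names.
#' @export
eeg_wavelet_power <- function(sig, freqs_hz = seq(2, 20, by = 1), n_cycles = 15) {
  stopifnot(inherits(sig, "raw_physio_signal"))
  if (sig$modality != "eeg_channel") stop("`sig` must have modality 'eeg_channel'")
  fs <- sig$fs_hz
  if (any(freqs_hz >= fs / 2)) stop("wavelet frequency at or above Nyquist")
  x <- sig$samples - mean(sig$samples)
  out <- matrix(0, length(x), length(freqs_hz))
  for (j in seq_along(freqs_hz)) {
    f0 <- freqs_hz[j]
    sigma_t <- n_cycles / (2 * pi * f0)
    half <- ceiling(3.5 * sigma_t * fs)
    tt <- seq(-half, half) / fs
    w <- exp(2i * pi * f0 * tt) * exp(-tt^2 / (2 * sigma_t^2))
    w <- w / sqrt(sum(Mod(w)^2))
    out[, j] <- Mod(fft_convolve_same_cplx(x, w))^2
  }
  colnames(out) <- freqs_hz
  out
}

#' Alpha-band amplitude envelope
#'
#' Hamming-window FIR bandpass (8-12 Hz) followed by the Hilbert envelope.
#'
#' @param sig A [raw_physio_signal()] with modality `"eeg_channel"`.
#' @param n_taps FIR length; see [fir_bandpass()] for the default.
#' @return Envelope series on the raw-signal grid.
#' @export
alpha_power <- function(sig, n_taps = NULL) {
  stopifnot(inherits(sig, "raw_physio_signal"))
  if (sig$modality != "eeg_channel") stop("`sig` must have modality 'eeg_channel'")
  if (sig$fs_hz < 24) stop("sampling rate too low for the 8-12 Hz band")
  xf <- fir_bandpass(sig$samples - mean(sig$samples), sig$fs_hz, 8, 12,
                     n_taps = n_taps)
  Mod(analytic_signal(xf))
}

#' Standardize a feature onto the fMRI frame grid
#'
#' The comparison pipeline applied to every extracted feature, in order:
#' clip at mean +/- 5 SD (outlier removal), resample to the fMRI frame
#' count, zero-phase fifth-order 0.01-0.1 Hz Butterworth bandpass.
#' Already-band-limited inputs (tonic skin conductance) can skip the final
#' filter.
#'
#' @param values Feature series on its native grid.
#' @param fs_hz Native sampling frequency (Hz).
#' @param n_frames fMRI frame count to resample to.
#' @param tr_s fMRI repetition time (s).
#' @param name,units Labels for the resulting [feature_series()].
#' @param clip_sd Clipping threshold in SDs (default 5).
#' @param filter Apply the 0.01-0.1 Hz bandpass (default TRUE).
#' @return A [feature_series()] of length `n_frames`.
#' @export
standardize_feature <- function(values, fs_hz, n_frames, tr_s,
                                name = "feature", units = "a.u.",
                                clip_sd = 5, filter = TRUE) {
  if (any(!is.finite(values))) stop("feature contains non-finite values")
  if (n_frames < 2) stop("`n_frames` must be at least 2")
  if (abs(length(values) / fs_hz - n_frames * tr_s) > max(tr_s, 1 / fs_hz) * 2) {
    stop(sprintf("feature duration (%.1f s) does not match the fMRI run (%.1f s)",
                 length(values) / fs_hz, n_frames * tr_s))
  }
  m <- mean(values); s <- stats::sd(values)
  x <- pmin(pmax(values, m - clip_sd * s), m + clip_sd * s)
  x <- resample_series(x, fs_hz, n_frames, fs_out = 1 / tr_s)
  if (filter) x <- bandpass_filter(x, 1 / tr_s)
  feature_series(x, tr_s, name = name, units = units)
}

#' Linearly interpolate blink gaps in a pupil recording
#'
#' @param sig A [raw_physio_signal()] with modality `"pupil"`; `NA` runs
#'   are treated as blinks.
#' @return The signal with gaps filled by linear interpolation (boundary
#'   values held at the ends).
#' @export
interpolate_blinks <- function(sig) {
  stopifnot(inherits(sig, "raw_physio_signal"))
  if (sig$modality != "pupil") stop("`sig` must have modality 'pupil'")
  x <- sig$samples
  if (!anyNA(x)) return(sig)
  good <- which(is.finite(x))
  if (length(good) < 2) stop("too few valid pupil samples to interpolate")
  x <- stats::approx(good, x[good], xout = seq_along(x), rule = 2)$y
  raw_physio_signal(x, sig$fs_hz, "pupil", sig$start_time_s)
}
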