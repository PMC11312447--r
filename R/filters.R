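# Digital filtering primitives: Butterworth IIR design (bilinear transform),
# zero-phase filtering with reflect padding, windowed-sinc FIR design, the
# analytic signal, and band-limited resampling. These back every filtering
# step in the package (0.01-0.1 Hz bandpass, PPG/respiration conditioning,
# alpha-band FIR).

# Expand a polynomial from its roots; returns coefficients in decreasing
# degree order, leading coefficient 1. Complex-safe.
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rt in r) p <- c(p, 0) - c(0, p * rt)
  p
}

#' Design a digital Butterworth filter
#'
#' Computes transfer-function coefficients for a lowpass, highpass or
#' bandpass Butterworth filter via the analog prototype and bilinear
#' transform, matching the standard engineering construction.
#'
#' @param order Filter order of the analog prototype. A bandpass design has
#'   digital order `2 * order`.
#' @param cutoff_hz Cutoff frequency in Hz (length 1 for low/highpass,
#'   length 2 `c(low, high)` for bandpass).
#' @param fs_hz Sampling frequency in Hz.
#' @param type One of `"low"`, `"high"`, `"band"`.
#' @return List with numerator `b` and denominator `a` coefficient vectors.
#' @export
butter_design <- function(order, cutoff_hz, fs_hz, type = c("low", "high", "band")) {
  zpk <- butter_zpk(order, cutoff_hz, fs_hz, match.arg(type))
  b <- Re(poly_from_roots(zpk$z)) * zpk$k
  a <- Re(poly_from_roots(zpk$p))
  list(b = b, a = a)
}

# digital Butterworth design in zero-pole-gain form (bilinear transform of
# the analog prototype)
butter_zpk <- function(order, cutoff_hz, fs_hz, type = c("low", "high", "band")) {
  type <- match.arg(type)
  if (order < 1 || order != round(order)) stop("`order` must be a positive integer")
  wn <- cutoff_hz / (fs_hz / 2)
  if (any(wn <= 0) || any(wn >= 1)) {
    stop("cutoff frequencies must lie strictly between 0 and the Nyquist frequency")
  }
  # analog prototype poles on the unit circle (Butterworth), gain 1
  k <- seq_len(order)
  p <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  z <- complex(0)
  gain <- 1
  fs2 <- 4  # bilinear with internal rate 2 (scipy convention)
  warped <- fs2 * tan(pi * wn / 2)
  if (type == "low") {
    p <- p * warped
    gain <- gain * warped^order
  } else if (type == "high") {
    gain <- gain * Re(prod(-p))
    p <- warped / p
    z <- rep(0 + 0i, order)
  } else {
    bw <- warped[2] - warped[1]
    w0 <- sqrt(warped[1] * warped[2])
    p <- p * bw / 2
    disc <- sqrt(p^2 - w0^2)
    p <- c(p + disc, p - disc)
    z <- rep(0 + 0i, order)
    gain <- gain * bw^order
  }
  # bilinear transform s -> z
  degree <- length(p) - length(z)
  zd <- (fs2 + z) / (fs2 - z)
  pd <- (fs2 + p) / (fs2 - p)
  zd <- c(zd, rep(-1 + 0i, degree))
  gd <- gain * Re(prod(fs2 - z) / prod(fs2 - p))
  list(z = zd, p = pd, k = gd)
}

#' Design a digital Butterworth filter as second-order sections
#'
#' Cascaded biquads are numerically stable at the extreme normalized
#' cutoffs this package needs (e.g. a 0.75 Hz lowpass on a 250 Hz
#' recording), where the expanded transfer-function form is not. Poles are
#' paired conjugate-by-conjugate (closest to the unit circle first) and
#' zeros (all at z = +/-1 for Butterworth) assigned nearest-first.
#'
#' @inheritParams butter_design
#' @return Matrix with one row per section: `b0 b1 b2 a0 a1 a2`.
#' @export
butter_sos <- function(order, cutoff_hz, fs_hz, type = c("low", "high", "band")) {
  zpk <- butter_zpk(order, cutoff_hz, fs_hz, match.arg(type))
  zpk_to_sos(zpk$z, zpk$p, zpk$k)
}

zpk_to_sos <- function(z, p, k) {
  # Butterworth digital zeros sit at z = +1 or z = -1 only; allocation is a
  # matter of counting
  n_plus <- sum(abs(z - 1) < 1e-8)
  n_minus <- sum(abs(z + 1) < 1e-8)
  if (n_plus + n_minus != length(z)) stop("unexpected zero locations")
  # conjugate pole pairs (upper half-plane representatives) + real poles,
  # poles closest to the unit circle in the last (outermost) sections
  pup <- p[Im(p) > 1e-12]
  pre <- Re(p[abs(Im(p)) <= 1e-12])
  pole_sets <- lapply(pup[order(abs(Mod(pup) - 1), decreasing = TRUE)],
                      function(q) c(q, Conj(q)))
  while (length(pre) > 0) {
    m <- min(2, length(pre))
    pole_sets[[length(pole_sets) + 1]] <- pre[seq_len(m)] + 0i
    pre <- pre[-seq_len(m)]
  }
  sos <- matrix(0, length(pole_sets), 6)
  for (s in seq_along(pole_sets)) {
    ps <- pole_sets[[s]]
    zs <- complex(0)
    for (j in seq_len(length(ps))) {
      if (n_plus > 0 && n_minus > 0) {
        # bandpass: give each section one zero at +1 and one at -1
        if (j == 1) { zs <- c(zs, 1 + 0i); n_plus <- n_plus - 1 }
        else { zs <- c(zs, -1 + 0i); n_minus <- n_minus - 1 }
      } else if (n_minus > 0) {
        zs <- c(zs, -1 + 0i); n_minus <- n_minus - 1
      } else if (n_plus > 0) {
        zs <- c(zs, 1 + 0i); n_plus <- n_plus - 1
      }
    }
    b <- Re(poly_from_roots(zs))
    a <- Re(poly_from_roots(ps))
    b <- c(b, rep(0, 3 - length(b)))
    a <- c(a, rep(0, 3 - length(a)))
    sos[s, ] <- c(b, a)
  }
  sos[1, 1:3] <- sos[1, 1:3] * k
  sos
}

# apply cascaded second-order sections, zero initial conditions
sos_filter <- function(sos, x) {
  for (s in seq_len(nrow(sos))) {
    x <- iir_filter(sos[s, 1:3], sos[s, 4:6], x)
  }
  x
}

# Direct-form IIR filtering, zero initial conditions.  The moving-average
# part runs through a one-sided convolution, the recursive part through
# stats::filter so long records stay fast.
iir_filter <- function(b, a, x) {
  b <- b / a[1]; a <- a / a[1]
  n <- length(x)
  v <- stats::filter(c(rep(0, length(b) - 1), x), b, method = "convolution", sides = 1)
  v <- as.numeric(v)[length(b):(length(b) - 1 + n)]
  if (length(a) > 1) {
    v <- as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  }
  v
}

#' Zero-phase filtering with reflect padding
#'
#' Applies an IIR filter forward and backward so the net phase response is
#' zero. The input is extended at both ends by odd reflection (length
#' `pad_factor * max(length(a), length(b))`) before filtering to suppress
#' edge transients.
#'
#' @param b,a Transfer-function coefficients (e.g. from [butter_design()]).
#' @param x Numeric signal.
#' @param pad_factor Reflect-pad length as a multiple of the filter length.
#' @return Filtered signal, same length as `x`.
#' @export
filtfilt_pad <- function(b, a, x, pad_factor = 3) {
  n <- length(x)
  npad <- min(n - 1, pad_factor * max(length(a), length(b)))
  if (npad < 1) stop("signal too short to filter")
  head_ref <- 2 * x[1] - x[seq(npad + 1, 2)]
  tail_ref <- 2 * x[n] - x[seq(n - 1, n - npad)]
  xe <- c(head_ref, x, tail_ref)
  y <- iir_filter(b, a, xe)
  y <- rev(iir_filter(b, a, rev(y)))
  y[(npad + 1):(npad + n)]
}

#' Zero-phase filtering of second-order sections with reflect padding
#'
#' Forward-backward application of a cascade from [butter_sos()]; odd
#' reflection of length `npad` at both ends suppresses edge transients.
#'
#' @param sos Section matrix from [butter_sos()].
#' @param x Numeric signal.
#' @param npad Reflect-pad length in samples (clipped to `length(x) - 1`).
#' @return Filtered signal, same length as `x`.
#' @export
filtfilt_sos <- function(sos, x, npad = 3 * nrow(sos) * 2) {
  n <- length(x)
  npad <- min(n - 1, npad)
  if (npad < 1) stop("signal too short to filter")
  head_ref <- 2 * x[1] - x[seq(npad + 1, 2)]
  tail_ref <- 2 * x[n] - x[seq(n - 1, n - npad)]
  xe <- c(head_ref, x, tail_ref)
  y <- sos_filter(sos, xe)
  y <- rev(sos_filter(sos, rev(y)))
  y[(npad + 1):(npad + n)]
}

# pad long enough for the slowest filter time constant: nominally 3x the
# filter length, stretched to two cycles of the lowest passband frequency
pad_samples <- function(order, fs_hz, f_low) {
  max(3 * (2 * order + 1), ceiling(2 * fs_hz / f_low))
}

#' Zero-phase Butterworth bandpass
#'
#' Designs a Butterworth bandpass as second-order sections and applies it
#' forward-backward. The package default (order 5, 0.01-0.1 Hz) is the
#' band used for all low-frequency arousal analyses.
#'
#' @param x Numeric signal.
#' @param fs_hz Sampling frequency (Hz).
#' @param low_hz,high_hz Band edges (Hz).
#' @param order Prototype order (default 5).
#' @return Filtered signal.
#' @export
bandpass_filter <- function(x, fs_hz, low_hz = 0.01, high_hz = 0.1, order = 5) {
  sos <- butter_sos(order, c(low_hz, high_hz), fs_hz, type = "band")
  # demean first so a constant input maps exactly to zero (no step transient)
  filtfilt_sos(sos, x - mean(x), pad_samples(order, fs_hz, low_hz))
}

#' Zero-phase Butterworth lowpass
#' @inheritParams bandpass_filter
#' @param cutoff_hz Cutoff (Hz).
#' @export
lowpass_filter <- function(x, fs_hz, cutoff_hz, order = 10) {
  sos <- butter_sos(order, cutoff_hz, fs_hz, type = "low")
  m <- mean(x)
  filtfilt_sos(sos, x - m, pad_samples(order, fs_hz, cutoff_hz)) + m
}

#' Analytic signal via the Hilbert transform
#'
#' Returns the complex analytic signal `x + i * H(x)` computed in the
#' frequency domain; `Mod()` of the result is the instantaneous amplitude
#' envelope and `Arg()` the instantaneous phase.
#'
#' @param x Real signal.
#' @return Complex vector, same length as `x`.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Linear-phase FIR bandpass (Hamming window), applied with zero net delay
#'
#' Windowed-sinc design; the symmetric kernel is applied by FFT convolution
#' and the group delay removed, so the output is zero-phase.
#'
#' @param x Signal.
#' @param fs_hz Sampling frequency (Hz).
#' @param low_hz,high_hz Band edges (Hz).
#' @param n_taps Number of filter taps (odd; default `round(3.3 * fs_hz) %/% 2 * 2 + 1`,
#'   a ~1 Hz transition width).
#' @return Filtered signal, same length as `x`.
#' @export
fir_bandpass <- function(x, fs_hz, low_hz, high_hz, n_taps = NULL) {
  if (is.null(n_taps)) n_taps <- round(3.3 * fs_hz) %/% 2 * 2 + 1
  if (n_taps %% 2 == 0) n_taps <- n_taps + 1
  if (length(x) <= n_taps) stop("signal shorter than the FIR filter; reduce `n_taps`")
  m <- (n_taps - 1) / 2
  t <- seq(-m, m)
  hi <- high_hz / fs_hz; lo <- low_hz / fs_hz
  kern <- 2 * hi * sinc(2 * hi * t) - 2 * lo * sinc(2 * lo * t)
  kern <- kern * (0.54 + 0.46 * cos(pi * t / m))  # Hamming
  # unit gain at band centre
  fc <- (low_hz + high_hz) / 2 / fs_hz
  kern <- kern / abs(sum(kern * exp(-2i * pi * fc * t)))
  fft_convolve_same(x, kern)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# centred FFT convolution returning a vector the length of x (edge-padded
# with reflected samples)
fft_convolve_same <- function(x, kern) {
  n <- length(x); m <- (length(kern) - 1) / 2
  npad <- min(n - 1, m)
  xe <- c(2 * x[1] - x[seq(npad + 1, 2)], x, 2 * x[n] - x[seq(n - 1, n - npad)])
  L <- stats::nextn(length(xe) + length(kern) - 1, 2)
  y <- Re(stats::fft(stats::fft(c(xe, rep(0, L - length(xe)))) *
                       stats::fft(c(kern, rep(0, L - length(kern)))), inverse = TRUE)) / L
  y[(npad + m + 1):(npad + m + n)]
}

# complex-valued variant used by the Morlet filter bank
fft_convolve_same_cplx <- function(x, kern) {
  n <- length(x); m <- (length(kern) - 1) / 2
  npad <- min(n - 1, m)
  xe <- c(2 * x[1] - x[seq(npad + 1, 2)], x, 2 * x[n] - x[seq(n - 1, n - npad)])
  L <- stats::nextn(length(xe) + length(kern) - 1, 2)
  y <- stats::fft(stats::fft(c(xe, rep(0, L - length(xe)))) *
                    stats::fft(c(kern, rep(0, L - length(kern)))), inverse = TRUE) / L
  y[(npad + m + 1):(npad + m + n)]
}

#' Shift a series in time by interpolation (edge-padded, never circular)
#'
#' A positive `lag_s` delays the series: `y(t) = x(t - lag_s)`. Values
#' requested beyond the recorded ends hold the boundary value.
#'
#' @param x Signal.
#' @param lag_s Shift in seconds (positive = delay).
#' @param fs_hz Sampling frequency (Hz).
#' @return Shifted signal, same length.
#' @export
shift_series <- function(x, lag_s, fs_hz) {
  n <- length(x)
  t <- seq(0, n - 1) / fs_hz
  tq <- pmin(pmax(t - lag_s, 0), (n - 1) / fs_hz)
  stats::spline(t, x, xout = tq, method = "fmm")$y
}

#' Resample a series to a target length
#'
#' When downsampling, anti-aliases with a zero-phase frequency-domain
#' lowpass (raised-cosine rolloff ending at the target Nyquist, applied to
#' the reflect-padded signal) -- stable at arbitrary decimation ratios
#' where a high-order IIR in transfer-function form is not -- then
#' evaluates a cubic interpolant on the target grid.
#'
#' @param x Signal at rate `fs_in`.
#' @param fs_in Input sampling frequency (Hz).
#' @param n_out Desired output length.
#' @param fs_out Output sampling frequency (Hz); default derived so the
#'   output spans the same duration.
#' @return Numeric vector of length `n_out`.
#' @export
resample_series <- function(x, fs_in, n_out, fs_out = NULL) {
  n <- length(x)
  if (is.null(fs_out)) fs_out <- n_out / (n / fs_in)
  if (fs_out < fs_in) {
    x <- fft_lowpass(x, fs_in, 0.9 * fs_out / 2, fs_out / 2)
  }
  t_in <- seq(0, n - 1) / fs_in
  t_out <- seq(0, n_out - 1) / fs_out
  t_out <- pmin(t_out, t_in[n])
  stats::spline(t_in, x, xout = t_out, method = "fmm")$y
}

# zero-phase frequency-domain lowpass: unity below `pass_hz`, raised-cosine
# taper to zero at `stop_hz`; reflect-padded to suppress edge ringing
fft_lowpass <- function(x, fs_hz, pass_hz, stop_hz) {
  n <- length(x)
  npad <- min(n - 1, n %/% 2)
  xe <- c(2 * x[1] - x[seq(npad + 1, 2)], x, 2 * x[n] - x[seq(n - 1, n - npad)])
  m <- length(xe)
  fr <- c(seq(0, floor(m / 2)), seq(-ceiling(m / 2) + 1, -1)) * fs_hz / m
  af <- abs(fr)
  gain <- ifelse(af <= pass_hz, 1,
                 ifelse(af >= stop_hz, 0,
                        0.5 * (1 + cos(pi * (af - pass_hz) / (stop_hz - pass_hz)))))
  y <- Re(stats::fft(stats::fft(xe) * gain, inverse = TRUE)) / m
  y[(npad + 1):(npad + n)]
}
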