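# Feature extraction: peak detection, interpolation-based series,
# respiratory volume, filters and the standardization contract.

make_pulse_train <- function(rate_hz = 1, fs = 100, dur = 60) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  u <- (t * rate_hz) %% 1
  raw_physio_signal(exp(-((u - 0.15) / 0.07)^2), fs, "ppg")
}

test_that("peak detector finds every pulse of a periodic train", {
  beats <- detect_ppg_peaks(make_pulse_train())
  expect_true(abs(length(beats$peak_times_s) - 60) <= 1)
  expect_true(all(abs(diff(beats$peak_times_s) - 1) < 0.02))
  expect_error(detect_ppg_peaks(raw_physio_signal(rep(1, 1000), 100, "ppg")),
               "flat|no peaks")
})

test_that("peak detector recovers >=99% of ground-truth systoles", {
  cfg <- synth_config(seed = 12)
  a <- generate_arousal(cfg)
  ph <- generate_physio(cfg, a)
  beats <- detect_ppg_peaks(ph$signals$ppg)
  d <- vapply(ph$truth$beat_times_s,
              function(b) min(abs(beats$peak_times_s - b)), numeric(1))
  expect_gte(mean(d < 0.05), 0.99)
})

test_that("heart rate: constant IBI, FC oracle match, boundary hold", {
  beats <- beat_series(0:59, rep(1, 60))
  hr <- heart_rate(beats, 10, 650)
  expect_true(all(abs(hr - 60) < 0.1))
  # alternating IBIs against the independent Fritsch-Carlson oracle
  tb <- cumsum(c(1, rep(c(0.8, 1.0), 15)))
  beats2 <- beat_series(tb, rep(1, length(tb)))
  hr2 <- heart_rate(beats2, 20, 600)
  probe_idx <- round(seq(100, 500, length.out = 10))
  t_probe <- (probe_idx - 1) / 20
  oracle <- fc_interp(tb[-1], 60 / diff(tb), t_probe)
  expect_equal(hr2[probe_idx], oracle, tolerance = 1e-8)
  expect_error(heart_rate(beat_series(1, 1), 10, 100), "2 beats")
})

test_that("ppg amplitude interpolates anchors and holds boundaries", {
  beats <- beat_series(seq(1, 50, by = 1), rep(2, 50))
  amp <- ppg_amplitude(beats, 10, 520)
  expect_true(all(abs(amp - 2) < 1e-10))
  tb <- seq(2, 58, by = 2)
  vals <- seq(1, 5, length.out = length(tb))
  beats2 <- beat_series(tb, vals)
  amp2 <- ppg_amplitude(beats2, 10, 600)
  probe_idx <- round(seq(50, 550, length.out = 10))
  oracle <- fc_interp(tb, vals, pmin(pmax((probe_idx - 1) / 10, tb[1]),
                                     tb[length(tb)]))
  expect_equal(amp2[probe_idx], oracle, tolerance = 1e-8)
  # interpolation property: anchors pass through exactly
  anchor_idx <- round(tb * 10) + 1
  expect_equal(amp2[anchor_idx], vals, tolerance = 1e-8)
  expect_error(ppg_amplitude(beat_series(numeric(0), numeric(0)), 10, 100),
               "2 beats")
})

test_that("respiratory volume matches the analytic value for pure tones", {
  fs <- 50
  t <- seq(0, 300 - 1 / fs, by = 1 / fs)
  sig <- raw_physio_signal(sin(2 * pi * 0.25 * t), fs, "respiration")
  rv <- respiratory_volume(sig)
  interior <- round(length(rv) * 0.1):round(length(rv) * 0.9)
  expect_true(all(abs(rv[interior] - 2 * pi * 0.25) / (2 * pi * 0.25) < 0.05))
  # chirp 0.15 -> 0.35 Hz with amplitude ramp 1 -> 2: RV tracks 2 pi f(t) A(t)
  f_t <- 0.15 + (0.35 - 0.15) * t / 300
  phase <- 2 * pi * cumsum(f_t) / fs
  A_t <- 1 + t / 300
  chirp <- raw_physio_signal(A_t * sin(phase), fs, "respiration")
  rv2 <- respiratory_volume(chirp)
  truth <- 2 * pi * f_t * A_t
  expect_gt(cor(rv2[interior], truth[interior]), 0.95)
  expect_error(respiratory_volume(raw_physio_signal(rep(0, 1000), fs,
                                                    "respiration")),
               "degenerate")
})

test_that("tonic skin conductance isolates the 0.01-0.1 Hz band", {
  fs <- 10
  t <- seq(0, 600 - 1 / fs, by = 1 / fs)
  inb <- tonic_skin_conductance(
    raw_physio_signal(sin(2 * pi * 0.05 * t), fs, "skin_conductance"))
  interior <- 1000:5000
  expect_gt(max(abs(inb[interior])), 0.95)
  cc <- stats::ccf(inb[interior], sin(2 * pi * 0.05 * t)[interior],
                   lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  outb <- tonic_skin_conductance(
    raw_physio_signal(sin(2 * pi * 0.5 * t), fs, "skin_conductance"))
  expect_lt(max(abs(outb[interior])), 0.05)
  dc <- tonic_skin_conductance(
    raw_physio_signal(rep(10, length(t)) + sin(2 * pi * 0.05 * t), fs,
                      "skin_conductance"))
  expect_lt(abs(mean(dc)), 0.02)
  expect_error(tonic_skin_conductance(
    raw_physio_signal(rnorm(500), 10, "skin_conductance")), "200 s")
})

test_that("wavelet power is frequency-selective with the default 2-20 Hz bank", {
  fs <- 250
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  sig <- raw_physio_signal(sin(2 * pi * 10 * t), fs, "eeg_channel")
  P <- eeg_wavelet_power(sig)
  freqs <- as.numeric(colnames(P))
  expect_equal(range(freqs), c(2, 20))
  interior <- 2000:5500
  expect_gt(mean(P[interior, freqs == 10]) / mean(P[interior, freqs == 2]), 20)
  # AM carrier: 10 Hz power envelope tracks the squared modulator
  mod <- 1 + 0.5 * sin(2 * pi * 0.2 * t)
  am <- raw_physio_signal(mod * sin(2 * pi * 10 * t), fs, "eeg_channel")
  Pam <- eeg_wavelet_power(am, freqs_hz = 10)
  expect_gt(cor(Pam[interior, 1], mod[interior]^2), 0.95)
  expect_error(eeg_wavelet_power(sig, freqs_hz = 200), "Nyquist")
})

test_that("alpha envelope follows a 10 Hz tone and rejects 4 Hz", {
  fs <- 250
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  env <- alpha_power(raw_physio_signal(2 * sin(2 * pi * 10 * t), fs,
                                       "eeg_channel"))
  interior <- 2000:5500
  expect_true(all(abs(env[interior] - 2) / 2 < 0.05))
  env4 <- alpha_power(raw_physio_signal(sin(2 * pi * 4 * t), fs,
                                        "eeg_channel"))
  expect_lt(max(env4[interior]), 0.1)
  env0 <- alpha_power(raw_physio_signal(rep(0, length(t)), fs, "eeg_channel"))
  expect_lt(max(env0), 1e-10)
})

test_that("standardize_feature clips, resamples and band-limits in order", {
  # clip rule: a 10 SD outlier is pulled to exactly mean + 5 SD
  set.seed(1)
  x <- rnorm(6000)
  m <- mean(x); s <- sd(x)
  x[3000] <- m + 10 * s
  clipped <- pmin(pmax(x, m - 5 * s), m + 5 * s)
  expect_equal(clipped[3000], m + 5 * s)
  f <- standardize_feature(x, 10, 600, 1)
  expect_length(f$values, 600)
  expect_s3_class(f, "feature_series")
  # 0.05 Hz tone at 100 Hz -> 1 Hz frame grid, amplitude preserved
  fs <- 100
  t <- seq(0, 600 - 1 / fs, by = 1 / fs)
  tone <- standardize_feature(sin(2 * pi * 0.05 * t), fs, 600, 1)
  t_out <- 0:599
  expect_lt(max(abs(tone$values[100:500] -
                      sin(2 * pi * 0.05 * t_out)[100:500])), 0.05)
  expect_error(standardize_feature(rnorm(1000), 100, 600, 1), "does not match")
})

test_that("blink interpolation fills pupil gaps linearly", {
  x <- sin(seq(0, 10, length.out = 1001))
  x[300:320] <- NA
  sig <- interpolate_blinks(raw_physio_signal(x, 100, "pupil"))
  expect_false(anyNA(sig$samples))
  expect_equal(sig$samples[310], (x[299] + x[321]) / 2, tolerance = 1e-3)
})
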