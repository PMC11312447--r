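# The generators: seeded reproducibility, spectral content, coupling
# structure, and the ground-truth contracts downstream oracles rely on.

test_that("arousal generator is reproducible, standardized and band-limited", {
  cfg <- synth_config(seed = 11)
  a1 <- generate_arousal(cfg)
  a2 <- generate_arousal(cfg)
  expect_identical(a1, a2)
  expect_lt(abs(mean(a1)), 1e-10)
  expect_equal(sd(a1), 1, tolerance = 1e-10)
  # periodogram oracle: power concentrated in 0.01-0.1 Hz
  sp <- stats::spec.pgram(stats::ts(a1, frequency = 1 / cfg$tr_s), plot = FALSE)
  frac <- sum(sp$spec[sp$freq >= 0.01 & sp$freq <= 0.1]) / sum(sp$spec)
  expect_gte(frac, 0.95)
  expect_error(generate_arousal(synth_config(duration_s = 150)), "2 cycles")
})

test_that("physio generator couples each modality at the configured lag", {
  cfg <- small_cfg(seed = 4)
  a <- generate_arousal(cfg)
  ph <- generate_physio(cfg, a)
  expect_true(all(diff(ph$truth$beat_times_s) > 0))
  # ground-truth beat-amplitude series vs arousal: negative extremum at the
  # configured +2 s lag (brute-force cross-correlation on the beat grid)
  bt <- ph$truth$beat_times_s
  amp <- ph$truth$beat_amplitudes
  lags <- seq(-6, 6, by = 1)
  a_fun <- stats::approxfun(seq_along(a) - 1, a, rule = 2)
  r <- vapply(lags, function(l) cor(amp, a_fun(bt - l)), numeric(1))
  expect_lt(min(r), -0.5)
  expect_lte(abs(lags[which.min(r)] - cfg$physio_couplings$ppg_amplitude$lag_s),
             cfg$tr_s)
  expect_error(generate_physio(cfg, rep(0.5, length(a))), "degenerate")
})

test_that("zero coupling gains decouple features from arousal", {
  cp <- default_couplings()
  for (nm in names(cp)) cp[[nm]]$gain <- 0
  cfg <- synth_config(duration_s = 400, n_voxels = 50, seed = 9,
                      physio_couplings = cp)
  a <- generate_arousal(cfg)
  ph <- generate_physio(cfg, a)
  amp <- ph$truth$beat_amplitudes
  bt <- ph$truth$beat_times_s
  a_fun <- stats::approxfun(seq_along(a) - 1, a, rule = 2)
  r <- vapply(seq(-6, 6), function(l) cor(amp, a_fun(bt - l)), numeric(1))
  # decoupled null: correlations stay inside a generous noise band
  expect_lt(max(abs(r)), 0.25)
})

test_that("fmri generator encodes the lag map and tissue signs", {
  cfg <- small_cfg(seed = 2)
  a <- generate_arousal(cfg)
  # noiseless, all lags zero: rank 1
  cfg0 <- synth_config(duration_s = 300, n_voxels = 40, seed = 2,
                       noise_sd = 0, voxel_lag_range_s = c(0, 0))
  fm0 <- generate_fmri(cfg0, a)
  sv <- svd(fm0$vts$data)$d
  expect_lt(sv[2] / sv[1], 1e-10)
  # csf voxels anti-correlated with arousal at lag 0
  csf <- fm0$truth$tissue == "csf"
  expect_true(all(cor(a, fm0$vts$data[, csf]) < 0))
  # configured lag map recovered by brute-force per-voxel cross-correlation
  cfgl <- synth_config(duration_s = 300, n_voxels = 40, seed = 5,
                       noise_sd = 0.1)
  fml <- generate_fmri(cfgl, a)
  lag_grid <- seq(0, 8, by = 0.5)
  a_fun <- stats::approxfun(seq_along(a) - 1, a, rule = 2)
  t_grid <- seq_along(a) - 1
  for (v in c(1, 10, 25, 40)) {
    r <- vapply(lag_grid, function(l) {
      cor(fml$vts$data[, v], fml$truth$voxel_sign[v] * a_fun(t_grid - l))
    }, numeric(1))
    expect_lte(abs(lag_grid[which.max(r)] - fml$truth$voxel_lag_s[v]),
               cfgl$tr_s)
  }
})

test_that("multi-echo generator obeys the monoexponential closed form", {
  cfg <- synth_config(duration_s = 300, n_voxels = 20, noise_sd = 0, seed = 3)
  a <- generate_arousal(cfg)
  me <- generate_multiecho(cfg, a, n_voxels = 12)
  # stored echoes match S0 * exp(-TE/T2*) at every frame/voxel
  for (e in seq_along(cfg$echo_times_ms)) {
    expected <- me$truth$s0_series * exp(-cfg$echo_times_ms[e] /
                                           me$truth$t2s_series_ms)
    expect_equal(me$me$data[, e, ], expected, tolerance = 1e-12)
  }
  # true T2* tracks arousal at the configured lag (construction check)
  v <- 1
  a_fun <- stats::approxfun(seq_along(a) - 1, a, rule = 2)
  t_grid <- seq_along(a) - 1
  lagged <- a_fun(t_grid - me$truth$voxel_lag_s[v])
  expect_gt(abs(cor(me$truth$t2s_series_ms[, v], lagged)), 0.99)
  expect_error(generate_multiecho(synth_config(echo_times_ms = 30), a),
               "2 echo")
  bad <- synth_config()
  bad$echo_times_ms <- c(-1, 30)
  expect_error(generate_multiecho(bad, a), "positive")
})

test_that("event generator: rate, jitter floor, and no-noise identity", {
  cfg0 <- synth_config(event_rate = 0)
  expect_equal(nrow(generate_events(cfg0)), 0)
  cfg <- synth_config(duration_s = 900, seed = 8)
  ev <- generate_events(cfg)
  expect_true(all(diff(ev$onset) >= 60 / cfg$event_rate * (1 - 0.369) - 1e-9))
  # fixed onsets, zero noise: event-locked average equals the waveform
  x <- rep(0, 300)
  onsets <- c(40, 120, 200)
  xi <- inject_events(x, onsets, tr_s = 1)
  seg <- sapply(onsets, function(on) xi[(on + 1):(on + 30)])
  expect_equal(rowMeans(seg), evoked_waveform(0:29), tolerance = 1e-12)
})

test_that("generate_dataset is bit-reproducible under a fixed seed", {
  cfg <- small_cfg(seed = 6)
  d1 <- generate_dataset(cfg, with_multiecho = FALSE)
  d2 <- generate_dataset(cfg, with_multiecho = FALSE)
  expect_identical(d1$arousal, d2$arousal)
  expect_identical(d1$fmri$data, d2$fmri$data)
  expect_identical(d1$signals$ppg$samples, d2$signals$ppg$samples)
  expect_identical(d1$events, d2$events)
})
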