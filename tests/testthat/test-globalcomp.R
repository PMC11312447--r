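# PCA/CPCA of voxel time series: preprocessing, component recovery, phase
# maps, and the phase-binned reconstruction.

test_that("preprocess_bold demeans, band-limits and can skip smoothing", {
  n <- 600
  const <- voxel_time_series(matrix(5, n, 3), 1)
  out <- preprocess_bold(const, smoothing_fwhm_mm = 0)
  expect_lt(max(abs(out$data)), 1e-8)
  t <- 0:(n - 1)
  X <- cbind(sin(2 * pi * 0.05 * t), sin(2 * pi * 0.3 * t))
  out2 <- preprocess_bold(voxel_time_series(X, 1), smoothing_fwhm_mm = 0)
  expect_gt(max(abs(out2$data[100:500, 1])), 0.9)
  expect_lt(max(abs(out2$data[100:500, 2])), 0.05)
  # smoothing disabled leaves spatial values untouched (vs smoothed changes)
  cfg <- small_cfg(seed = 1)
  fm <- generate_fmri(cfg, generate_arousal(cfg))
  p0 <- preprocess_bold(fm$vts, smoothing_fwhm_mm = 0)
  p5 <- preprocess_bold(fm$vts, smoothing_fwhm_mm = 5)
  expect_false(isTRUE(all.equal(p0$data, p5$data)))
  expect_error(preprocess_bold(voxel_time_series(matrix(rnorm(300), 100, 3), 1),
                               0), "2 cycles")
})

test_that("fit_pca recovers a rank-1 structure and applies the sign flip", {
  set.seed(3)
  n <- 400; nv <- 120
  w_true <- rnorm(nv); w_true <- w_true / sqrt(sum(w_true^2))
  s_true <- as.numeric(scale(bandpass_filter(rnorm(n), 1)))
  X <- s_true %*% t(w_true)
  vts <- voxel_time_series(X, 1)
  pc <- fit_pca(vts, zscore_runs = FALSE)
  expect_equal(abs(sum(pc$weights * w_true)), 1, tolerance = 1e-10)
  expect_equal(pc$explained_variance_ratio, 1, tolerance = 1e-10)
  # rank-1 + noise at SNR 2 (amplitude): cosine >= 0.99
  Xn <- X + matrix(rnorm(n * nv, sd = sd(X) / 2), n, nv)
  pcn <- fit_pca(voxel_time_series(Xn, 1), zscore_runs = FALSE)
  expect_gte(abs(sum(pcn$weights * w_true)), 0.99)
  # gray voxels constructed anti-correlated with the latent still end
  # positive after the sign flip
  tissue <- rep(c("gray", "csf"), each = nv / 2)
  Xg <- cbind(-X[, 1:(nv / 2)], X[, (nv / 2 + 1):nv])
  pg <- fit_pca(voxel_time_series(Xg, 1, tissue_label = tissue),
                zscore_runs = FALSE)
  expect_gt(mean(pg$weights[tissue == "gray"]), 0)
})

test_that("exact and randomized solvers agree on desk-scale matrices", {
  set.seed(8)
  cfg <- small_cfg(seed = 8)
  fm <- generate_fmri(cfg, generate_arousal(cfg))
  vts <- preprocess_bold(fm$vts, 0)
  pe <- fit_pca(vts, solver = "exact")
  pr <- fit_pca(vts, solver = "randomized")
  expect_lt(max(abs(abs(pe$scores) - abs(pr$scores))), 1e-8)
})

test_that("PC1 scores track the global mean time course", {
  cfg <- synth_config(duration_s = 600, n_voxels = 400, seed = 10)
  fm <- generate_fmri(cfg, generate_arousal(cfg))
  vts <- preprocess_bold(fm$vts, 0)
  pc <- fit_pca(vts)
  gm <- rowMeans(vts$data[, fm$truth$voxel_sign > 0])
  expect_gt(abs(cor(pc$scores, gm)), 0.9)
})

test_that("fit_cpca: zero-lag data gives a flat phase map, EVR 1 noiseless", {
  n <- 500
  X <- traveling_wave(n, rep(0, 60))
  cp <- fit_cpca(voxel_time_series(X, 1), zscore_runs = FALSE)
  ph <- cp$phase_delay_map
  # circular SD < 0.01 rad
  R <- Mod(mean(exp(1i * ph)))
  expect_lt(sqrt(-2 * log(R)), 0.01)
  expect_equal(cp$explained_variance_ratio, 1, tolerance = 0.01)
})

test_that("fit_cpca recovers a traveling-wave phase gradient", {
  set.seed(5)
  lags <- runif(300, 0, 6)
  X <- traveling_wave(600, lags, noise_sd = 0.5, seed = 5)
  cp <- fit_cpca(voxel_time_series(X, 1), zscore_runs = FALSE)
  expect_gte(abs(circ_cor(cp$phase_delay_map, 2 * pi * 0.05 * lags)), 0.95)
  # invariance to a global time shift: phase offsets only
  Xs <- traveling_wave(600, lags + 1.5, noise_sd = 0.5, seed = 5)
  cps <- fit_cpca(voxel_time_series(Xs, 1), zscore_runs = FALSE)
  dphi <- (cps$phase_delay_map - cp$phase_delay_map) %% (2 * pi)
  R <- Mod(mean(exp(1i * dphi)))
  expect_gt(R, 0.9)  # concentrated phase offset
})

test_that("reconstruct_movie averages the component projection per phase bin", {
  lags <- seq(0, 6, length.out = 80)
  # incommensurate carrier so score phases cover [0, 2pi) (a 20-samples-
  # per-cycle carrier hits only 20 discrete phases and leaves bins empty)
  X <- traveling_wave(1200, lags, noise_sd = 0.02, f0 = 0.0483, seed = 2)
  cp <- fit_cpca(voxel_time_series(X, 1), zscore_runs = FALSE)
  mv <- reconstruct_movie(cp, 30)
  expect_equal(nrow(mv$maps), 30)
  # analytic projection oracle: map at bin center phi ~ Re(weights e^{i phi})
  for (b in seq(1, 30, by = 4)) {
    oracle <- Re(Conj(cp$weights) * exp(1i * mv$bin_centers[b]))
    expect_gte(abs(cor(mv$maps[b, ], oracle)), 0.99)
  }
  # zero-lag component with a spatial amplitude pattern: every map is
  # proportional to that one pattern
  set.seed(3)
  amp <- runif(40, 0.5, 2)
  s0 <- sin(2 * pi * 0.0483 * (0:1199))
  X0 <- outer(s0, amp)
  cp0 <- fit_cpca(voxel_time_series(X0, 1), zscore_runs = FALSE)
  mv0 <- reconstruct_movie(cp0, 10)
  cors <- abs(cor(t(mv0$maps)))
  expect_true(all(cors[upper.tri(cors)] >= 0.99))
  expect_error(reconstruct_movie(cp, 500), "empty")
})
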