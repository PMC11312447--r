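# Log-linear T2*/S0 fitting, cardiac phase regressors and max-R2 slice
# selection.

make_me <- function(s0, t2s, te = c(13.7, 30, 47), n = 5, noise_sd = 0) {
  nv <- length(s0)
  data <- array(0, c(n, length(te), nv))
  for (e in seq_along(te)) {
    clean <- matrix(rep(s0 * exp(-te[e] / t2s), each = n), n, nv)
    if (noise_sd > 0) clean <- clean * exp(rnorm(n * nv, sd = noise_sd))
    data[, e, ] <- clean
  }
  multi_echo_series(data, te, tr_s = 1)
}

test_that("noiseless 3-echo data returns S0 and T2* to machine precision", {
  me <- make_me(s0 = c(1000, 800), t2s = c(30, 45))
  fit <- fit_decay(me)
  expect_true(all(fit$valid))
  expect_equal(unique(round(fit$t2s_ms[, 1], 9)), 30)
  expect_equal(unique(round(fit$s0[, 1], 6)), 1000)
  expect_equal(fit$t2s_ms[1, 2], 45, tolerance = 1e-9)
  expect_equal(fit$s0[1, 2], 800, tolerance = 1e-6)
})

test_that("fit is scale-equivariant and interpolates with two echoes", {
  me <- make_me(s0 = 500, t2s = 40)
  f1 <- fit_decay(me)
  me$data <- me$data * 3
  f2 <- fit_decay(me)
  expect_equal(f2$s0, 3 * f1$s0, tolerance = 1e-10)
  expect_equal(f2$t2s_ms, f1$t2s_ms, tolerance = 1e-10)
  # 2 echoes: exact interpolation, zero residuals
  me2 <- make_me(s0 = 900, t2s = 35, te = c(15, 40))
  f3 <- fit_decay(me2)
  resid <- me2$data[1, , 1] - f3$s0[1, 1] * exp(-c(15, 40) / f3$t2s_ms[1, 1])
  expect_lt(max(abs(resid)), 1e-9)
})

test_that("nonpositive samples and nonphysical slopes invalidate the fit", {
  me <- make_me(s0 = c(1000, 1000), t2s = c(30, 30))
  me$data[2, 1, 1] <- 0
  fit <- fit_decay(me)
  expect_false(fit$valid[2, 1])
  expect_true(fit$valid[1, 1])
  # increasing signal with TE (slope >= 0) is flagged
  me$data[3, , 2] <- c(100, 200, 400)
  expect_false(fit_decay(me)$valid[3, 2])
})

test_that("noisy fits match the nonlinear least-squares oracle", {
  set.seed(1)
  n <- 1000
  me <- make_me(s0 = 1000, t2s = 30, n = n, noise_sd = 0.02)
  fit <- fit_decay(me)
  med <- median(fit$t2s_ms[fit$valid[, 1], 1])
  expect_lt(abs(med - 30) / 30, 0.02)
  # independent NLS oracle on a subsample of frames
  te <- me$echo_times_ms
  nls_t2s <- vapply(seq(1, n, by = 10), function(f) {
    y <- me$data[f, , 1]
    fitn <- stats::nls(y ~ s0 * exp(-te / t2), start = list(s0 = 900, t2 = 25))
    coef(fitn)[["t2"]]
  }, numeric(1))
  expect_lt(abs(med - median(nls_t2s)) / median(nls_t2s), 0.03)
})

test_that("cardiac phase is linear within each beat interval", {
  beats <- beat_series(c(0, 1, 2.5, 3.5), rep(1, 4))
  cp <- cardiac_phase(beats, frame_times_s = c(1, 1.75, 3))
  expect_equal(cp$phase[1, 1], 0, tolerance = 1e-12)           # at a beat
  expect_equal(cp$phase[2, 1], pi, tolerance = 1e-10)          # IBI midpoint
  expect_equal(cp$phase[3, 1], 2 * pi * 0.5 / 1, tolerance = 1e-10)
  expect_error(cardiac_phase(beats, frame_times_s = 10), "outside")
  # irregular beats: regressors equal the brute-force evaluation
  set.seed(2)
  tb <- cumsum(runif(50, 0.7, 1.3))
  bs <- beat_series(tb, rep(1, 50))
  ft <- seq(tb[2], tb[45], length.out = 20)
  cp2 <- cardiac_phase(bs, ft, order = 2)
  for (i in seq_along(ft)) {
    k <- max(which(tb <= ft[i]))
    phi <- 2 * pi * (ft[i] - tb[k]) / (tb[k + 1] - tb[k])
    expect_equal(cp2$regressors[[1]][i, ],
                 c(cos(phi), sin(phi), cos(2 * phi), sin(2 * phi)),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("max-R2 slice selection: in-span signal, max property, null level", {
  set.seed(3)
  tb <- cumsum(runif(220, 0.8, 1.2))
  bs <- beat_series(tb, rep(1, 220))
  ft <- seq(tb[2], tb[2] + 199, length.out = 200)
  cp <- cardiac_phase(bs, ft, slice_timing_s = c(0, 0.2, 0.4), order = 2)
  # voxel = cos(own-slice phase): R2 ~ 1
  y1 <- cos(cp$phase[, 2])
  out <- max_slice_r2(cbind(y1), cp)
  expect_gte(out$r2[1], 0.999)
  expect_equal(out$best_slice[1], 2)
  # max over slices >= any single slice's fit by construction
  y2 <- cos(cp$phase[, 1] + 0.7)
  X <- cbind(1, cp$regressors[[3]])
  fit3 <- lm.fit(X, y2)
  r2_slice3 <- 1 - sum(fit3$residuals^2) / sum((y2 - mean(y2))^2)
  expect_gte(max_slice_r2(cbind(y2), cp)$r2[1], r2_slice3 - 1e-12)
  # constant voxel: flagged, R2 = 0
  outc <- max_slice_r2(cbind(rep(2, 200)), cp)
  expect_true(outc$degenerate[1])
  expect_equal(outc$r2[1], 0)
  # white-noise voxels: mean R2 near the analytic null expectation
  # E[R2] ~ p/(n-1) with p = 4 regressors, max over 3 correlated slices;
  # Monte-Carlo oracle bound computed from the simulation itself
  set.seed(4)
  Yn <- matrix(rnorm(200 * 400), 200, 400)
  r2n <- max_slice_r2(Yn, cp)$r2
  expect_gt(mean(r2n), 4 / 199 * 0.8)
  expect_lt(mean(r2n), 3 * 4 / 199 * 1.5)
})
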