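# Independent oracles and small fixture builders shared across tests.

# Fritsch-Carlson (1980) monotone cubic interpolation, implemented from the
# published algorithm independently of stats::splinefun
fc_interp <- function(x, y, xq) {
  n <- length(x); h <- diff(x); d <- diff(y) / h
  m <- numeric(n)
  m[1] <- d[1]; m[n] <- d[n - 1]
  for (i in 2:(n - 1)) m[i] <- (d[i - 1] + d[i]) / 2
  for (i in 1:(n - 1)) {
    if (d[i] == 0) {
      m[i] <- m[i + 1] <- 0
    } else {
      a <- m[i] / d[i]; b <- m[i + 1] / d[i]
      s <- a^2 + b^2
      if (s > 9) {
        t <- 3 / sqrt(s); m[i] <- t * a * d[i]; m[i + 1] <- t * b * d[i]
      }
    }
  }
  vapply(xq, function(q) {
    i <- max(1, min(n - 1, findInterval(q, x)))
    t <- (q - x[i]) / h[i]
    (2 * t^3 - 3 * t^2 + 1) * y[i] + (t^3 - 2 * t^2 + t) * h[i] * m[i] +
      (-2 * t^3 + 3 * t^2) * y[i + 1] + (t^3 - t^2) * h[i] * m[i + 1]
  }, numeric(1))
}

# Fisher-Lee circular correlation between two angle vectors
circ_cor <- function(a, b) {
  A <- a - atan2(mean(sin(a)), mean(cos(a)))
  B <- b - atan2(mean(sin(b)), mean(cos(b)))
  sum(sin(A) * sin(B)) / sqrt(sum(sin(A)^2) * sum(sin(B)^2))
}

# band-limited (0.01-0.1 Hz) unit-variance noise on a 1 Hz frame grid
inband_noise <- function(n, seed) {
  set.seed(seed)
  as.numeric(scale(bandpass_filter(rnorm(n), 1)))
}

# noiseless traveling wave: 0.05 Hz carrier with per-voxel lags
traveling_wave <- function(n_frames, lags_s, noise_sd = 0, f0 = 0.05,
                           seed = 1) {
  set.seed(seed)
  t <- seq_len(n_frames) - 1
  X <- vapply(lags_s, function(d) sin(2 * pi * f0 * (t - d)), numeric(n_frames))
  if (noise_sd > 0) {
    X <- X + matrix(rnorm(n_frames * length(lags_s), sd = noise_sd),
                    n_frames, length(lags_s))
  }
  X
}

small_cfg <- function(seed = 1, ...) {
  synth_config(duration_s = 300, n_voxels = 200, seed = seed, ...)
}
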