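# Pairwise lead-lag structure between the global signal and each
# physiological/EEG feature: frame-lag cross-correlation curves on a common
# +/-30 s spline grid, their group average, and impulse-response estimation
# by deconvolution under a Gaussian-process (squared-exponential) prior.

#' Cross-correlation curve between two frame-grid series
#'
#' Computes the product-moment correlation `r(i) = cor(x[t+i], y[t])` at
#' every integer frame lag within `max_lag_s`, over the overlapping
#' segment, then interpolates the curve with a cubic spline onto a common
#' 1 s grid spanning `[-max_lag_s, +max_lag_s]`. With `x` the global fMRI
#' signal and `y` a physiological signal, strong correlation at a positive
#' lag means the global signal lags (follows) the physiological signal.
#'
#' @param x,y [feature_series()] objects (equal length and TR); `x` is the
#'   series that is shifted.
#' @param max_lag_s Maximum lag (s), default 30.
#' @return A `crosscorr_curve`: `lags_s` (1 s grid), `r`, `frame_lags_s`,
#'   `frame_r`, `pair`.
#' @export
cross_correlate <- function(x, y, max_lag_s = 30) {
  xv <- if (inherits(x, "feature_series")) x$values else as.numeric(x)
  yv <- if (inherits(y, "feature_series")) y$values else as.numeric(y)
  tr <- if (inherits(x, "feature_series")) x$tr_s else y$tr_s
  if (length(xv) != length(yv)) stop("series must have equal length")
  n <- length(xv)
  max_lag <- floor(max_lag_s / tr)
  if (n - max_lag < 10) stop("insufficient overlap at the maximum lag")
  lags <- seq(-max_lag, max_lag)
  r <- vapply(lags, function(i) {
    if (i >= 0) {
      xs <- xv[(1 + i):n]; ys <- yv[1:(n - i)]
    } else {
      xs <- xv[1:(n + i)]; ys <- yv[(1 - i):n]
    }
    if (stats::sd(xs) < 1e-14 || stats::sd(ys) < 1e-14) {
      stop("zero-variance overlap segment in cross-correlation")
    }
    stats::cor(xs, ys)
  }, numeric(1))
  grid <- seq(-max_lag_s, max_lag_s, by = 1)
  ri <- stats::spline(lags * tr, r, xout = pmin(pmax(grid, min(lags) * tr),
                                               max(lags) * tr))$y
  structure(list(lags_s = grid, r = pmin(pmax(ri, -1), 1),
                 frame_lags_s = lags * tr, frame_r = r,
                 pair = c(x_name(x), x_name(y))),
            class = "crosscorr_curve")
}

x_name <- function(x) if (inherits(x, "feature_series")) x$name else "series"

#' Group-average cross-correlation curve
#'
#' Pointwise mean of subject-level curves sharing a lag grid.
#'
#' @param curves List of `crosscorr_curve` objects.
#' @return A `crosscorr_curve` with the averaged `r`.
#' @export
group_average <- function(curves) {
  if (length(curves) == 0) stop("empty set of curves")
  lags <- curves[[1]]$lags_s
  for (cv in curves) {
    if (!isTRUE(all.equal(cv$lags_s, lags))) stop("curves must share a lag grid")
  }
  rmat <- vapply(curves, function(cv) cv$r, numeric(length(lags)))
  structure(list(lags_s = lags, r = rowMeans(rmat),
                 frame_lags_s = curves[[1]]$frame_lags_s,
                 frame_r = rowMeans(vapply(curves, function(cv) cv$frame_r,
                                           numeric(length(curves[[1]]$frame_r)))),
                 pair = curves[[1]]$pair, level = "group"),
            class = "crosscorr_curve")
}

# lagged design matrix: column j holds input(t - tau_j), edge-held
lagged_design <- function(p, lag_grid_s, tr_s) {
  n <- length(p)
  t <- seq(0, n - 1) * tr_s
  f <- stats::approxfun(t, p, rule = 2)
  vapply(lag_grid_s, function(tau) f(t - tau), numeric(n))
}

#' Impulse response by deconvolution with a Gaussian-process prior
#'
#' Models the output series as a lagged linear convolution of the input,
#' `g(t) = sum_tau h(tau) p(t - tau) + e`, with a zero-mean GP prior on the
#' kernel `h` (squared-exponential covariance; length scale in lag-grid
#' samples, default 3; variance default 1). The returned `h` is the MAP /
#' posterior-mean solution `K A' (A K A' + sigma2 I)^-1 g`; the noise
#' variance `sigma2` is selected by maximizing the GP marginal likelihood
#' over a log-spaced grid unless supplied. Negative lags in `lag_grid_s`
#' capture response components preceding the input impulse.
#'
#' @param output The response series (by default the global fMRI signal);
#'   a [feature_series()] or numeric vector.
#' @param input The impulse-bearing series (physiological signal).
#' @param lag_grid_s Lag grid (s), strictly increasing, spanning negative
#'   and positive lags; default `seq(-10, 30)` at the series TR.
#' @param length_scale GP length scale in lag-grid samples (default 3).
#' @param kernel_variance GP kernel variance (default 1).
#' @param sigma2 Optional fixed noise variance; 0 demands a well-
#'   conditioned design and errors otherwise.
#' @param n_sigma2 Grid size for marginal-likelihood selection.
#' @return An `impulse_response`: `lags_s`, `h`, `length_scale`,
#'   `kernel_variance`, `noise_variance`, `marginal_loglik`.
#' @export
estimate_irf <- function(output, input, lag_grid_s = NULL, length_scale = 3,
                         kernel_variance = 1, sigma2 = NULL, n_sigma2 = 20) {
  g <- if (inherits(output, "feature_series")) output$values else as.numeric(output)
  p <- if (inherits(input, "feature_series")) input$values else as.numeric(input)
  tr <- if (inherits(output, "feature_series")) output$tr_s else 1
  if (length(g) != length(p)) stop("series must have equal length")
  if (is.null(lag_grid_s)) lag_grid_s <- seq(-10, 30, by = tr)
  if (any(diff(lag_grid_s) <= 0)) stop("`lag_grid_s` must be strictly increasing")
  A <- lagged_design(p, lag_grid_s, tr)
  m <- length(lag_grid_s)
  idx <- seq_len(m)
  K <- kernel_variance * exp(-0.5 * outer(idx, idx, `-`)^2 / length_scale^2)
  G <- A %*% K %*% t(A)
  eg <- eigen(G, symmetric = TRUE)
  proj <- as.numeric(t(eg$vectors) %*% g)
  n <- length(g)
  if (!is.null(sigma2) && sigma2 == 0) {
    if (min(eg$values) < 1e-10 * max(eg$values)) {
      stop("design is ill-conditioned with sigma2 = 0; supply sigma2 > 0")
    }
  }
  if (is.null(sigma2)) {
    vg <- stats::var(g)
    grid <- exp(seq(log(1e-6 * vg), log(10 * vg), length.out = n_sigma2))
    ll <- vapply(grid, function(s2) {
      lam <- eg$values + s2
      -0.5 * sum(proj^2 / lam) - 0.5 * sum(log(lam)) - 0.5 * n * log(2 * pi)
    }, numeric(1))
    sigma2 <- grid[which.max(ll)]
    mll <- max(ll)
  } else {
    lam <- eg$values + sigma2
    mll <- -0.5 * sum(proj^2 / lam) - 0.5 * sum(log(lam)) - 0.5 * n * log(2 * pi)
  }
  alpha <- eg$vectors %*% (proj / (eg$values + sigma2))
  h <- as.numeric(K %*% t(A) %*% alpha)
  structure(list(lags_s = lag_grid_s, h = h, length_scale = length_scale,
                 kernel_variance = kernel_variance, noise_variance = sigma2,
                 marginal_loglik = mll),
            class = "impulse_response")
}

#' Write a cross-correlation curve or impulse response as TSV
#' @param obj A `crosscorr_curve` or `impulse_response`.
#' @param path Output path.
#' @export
write_curve_tsv <- function(obj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(obj, "crosscorr_curve")) {
    writeLines(c(sprintf("# pair=%s~%s", obj$pair[1], obj$pair[2]),
                 "lag_s\tr"), con)
    writeLines(sprintf("%g\t%.10g", obj$lags_s, obj$r), con)
  } else {
    writeLines(c(sprintf("# length_scale=%g kernel_variance=%g noise_variance=%g",
                         obj$length_scale, obj$kernel_variance,
                         obj$noise_variance),
                 "lag_s\th"), con)
    writeLines(sprintf("%g\t%.10g", obj$lags_s, obj$h), con)
  }
  invisible(path)
}
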