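# Spatiotemporal structure of the global fMRI signal: zero-lag structure by
# PCA and time-lag (traveling-wave) structure by complex PCA of the
# analytic signal, with the phase-delay map and the phase-binned temporal
# reconstruction ("movie").

#' Preprocess voxel time series
#'
#' Optional separable Gaussian spatial smoothing on the mask lattice,
#' zero-phase fifth-order 0.01-0.1 Hz temporal bandpass, then per-voxel
#' demeaning.
#'
#' @param vts A [voxel_time_series()].
#' @param smoothing_fwhm_mm Gaussian kernel FWHM in mm (0 disables;
#'   default 5). Requires a lattice `mask` and `pixdim_mm`.
#' @param pixdim_mm Voxel size (mm) for the smoothing kernel.
#' @param low_hz,high_hz Temporal band edges (Hz).
#' @return A preprocessed [voxel_time_series()].
#' @export
preprocess_bold <- function(vts, smoothing_fwhm_mm = 5, pixdim_mm = 3,
                            low_hz = 0.01, high_hz = 0.1) {
  stopifnot(inherits(vts, "voxel_time_series"))
  n <- nrow(vts$data)
  if (n * vts$tr_s < 2 / low_hz) {
    stop(sprintf("run shorter than 2 cycles at %.3g Hz", low_hz))
  }
  data <- vts$data
  if (smoothing_fwhm_mm > 0) {
    if (is.null(vts$mask)) stop("spatial smoothing requires a lattice mask")
    data <- smooth_on_lattice(data, vts$mask, smoothing_fwhm_mm / pixdim_mm)
  }
  sos <- butter_sos(5, c(low_hz, high_hz), 1 / vts$tr_s, type = "band")
  npad <- pad_samples(5, 1 / vts$tr_s, low_hz)
  data <- sweep(data, 2, colMeans(data))  # no step transient for constants
  for (v in seq_len(ncol(data))) data[, v] <- filtfilt_sos(sos, data[, v], npad)
  data <- sweep(data, 2, colMeans(data))
  voxel_time_series(data, vts$tr_s, vts$mask, vts$tissue_label, vts$subject_id)
}

# separable Gaussian smoothing of frames x voxels data over an integer
# lattice; voxels outside the mask do not contribute (masked convolution
# with kernel renormalization)
smooth_on_lattice <- function(data, coords, fwhm_vox) {
  sigma <- fwhm_vox / (2 * sqrt(2 * log(2)))
  if (sigma <= 0) return(data)
  dims <- apply(coords, 2, max)
  half <- max(1L, ceiling(3 * sigma))
  kern <- stats::dnorm(seq(-half, half), sd = sigma)
  kern <- kern / sum(kern)
  vol <- array(0, dims)
  wt <- array(0, dims)
  wt[coords] <- 1
  wts <- convolve_sep3d(wt, kern)
  out <- data
  for (f in seq_len(nrow(data))) {
    vol[] <- 0
    vol[coords] <- data[f, ]
    sm <- convolve_sep3d(vol, kern)
    out[f, ] <- (sm / pmax(wts, 1e-12))[coords]
  }
  out
}

convolve_sep3d <- function(vol, kern) {
  d <- dim(vol)
  half <- (length(kern) - 1) / 2
  conv1 <- function(m) {
    # convolve each column of a matrix with kern, zero-padded
    n <- nrow(m)
    mp <- rbind(matrix(0, half, ncol(m)), m, matrix(0, half, ncol(m)))
    out <- stats::filter(mp, kern, method = "convolution", sides = 2)
    out[(half + 1):(half + n), , drop = FALSE]
  }
  v <- array(conv1(matrix(vol, d[1])), d)
  v <- aperm(array(conv1(matrix(aperm(v, c(2, 1, 3)), d[2])), d[c(2, 1, 3)]),
             c(2, 1, 3))
  aperm(array(conv1(matrix(aperm(v, c(3, 1, 2)), d[3])), d[c(3, 1, 2)]),
        c(2, 3, 1))
}

concat_runs <- function(data, zscore_runs = TRUE) {
  if (inherits(data, "voxel_time_series")) data <- list(data)
  nv <- ncol(data[[1]]$data)
  tissue <- data[[1]]$tissue_label
  for (d in data) {
    if (ncol(d$data) != nv) stop("voxel mask mismatch across runs")
  }
  mats <- lapply(data, function(d) {
    m <- sweep(d$data, 2, colMeans(d$data))
    if (zscore_runs) {
      s <- apply(m, 2, stats::sd)
      m <- sweep(m, 2, pmax(s, 1e-12), `/`)
    }
    m
  })
  list(X = do.call(rbind, mats), tissue = tissue, tr_s = data[[1]]$tr_s)
}

# simple randomized range-finder SVD (real or complex), for parity checks
# with the exact solver on desk-scale matrices
randomized_svd <- function(X, k = 1, n_oversample = 10, n_iter = 4, seed = 1) {
  set.seed(seed)
  p <- ncol(X)
  l <- min(p, k + n_oversample)
  Omega <- matrix(stats::rnorm(p * l), p, l)
  if (is.complex(X)) Omega <- Omega + 1i * matrix(stats::rnorm(p * l), p, l)
  Y <- X %*% Omega
  for (i in seq_len(n_iter)) Y <- X %*% Conj(t(Conj(t(Y)) %*% X))
  Q <- qr.Q(qr(Y))
  B <- Conj(t(Q)) %*% X
  s <- svd(B, nu = k, nv = k)
  list(u = Q %*% s$u, d = s$d, v = s$v)
}

#' First principal component of voxel time series
#'
#' SVD of the temporally concatenated frames x voxels matrix (runs demeaned
#' and, by default, z-scored in time before concatenation). The component
#' sign is flipped so the mean weight over gray-labeled voxels is positive,
#' matching the convention that positive scores mean positive cortical
#' signal and negative CSF signal.
#'
#' @param data A [voxel_time_series()] or list of them (shared mask).
#' @param zscore_runs Z-score each run's voxels in time before
#'   concatenation (default TRUE).
#' @param solver `"exact"` (LAPACK SVD) or `"randomized"`.
#' @return A `real_component`: `weights` (unit norm), `scores`,
#'   `explained_variance_ratio`, `sign_convention`.
#' @export
fit_pca <- function(data, zscore_runs = TRUE, solver = c("exact", "randomized")) {
  solver <- match.arg(solver)
  cr <- concat_runs(data, zscore_runs)
  X <- cr$X
  s <- if (solver == "exact") svd(X, nu = 1, nv = 1) else randomized_svd(X, 1)
  w <- s$v[, 1]
  scores <- as.numeric(X %*% w)
  flip <- component_sign(w, cr$tissue)
  total_var <- sum(X^2)
  structure(list(weights = flip * w, scores = flip * scores,
                 explained_variance_ratio = s$d[1]^2 / total_var,
                 sign_convention = "gray-mean-positive",
                 tr_s = cr$tr_s, tissue_label = cr$tissue),
            class = "real_component")
}

component_sign <- function(w, tissue) {
  ref <- if (!is.null(tissue) && any(tissue == "gray")) {
    mean(Re(w[tissue == "gray"]))
  } else {
    mean(Re(w))
  }
  if (ref < 0) -1 else 1
}

#' First complex principal component (traveling-wave structure)
#'
#' Forms the per-voxel analytic signal (Hilbert transform along time),
#' takes the complex SVD of the frames x voxels matrix, and returns the
#' first component. The per-voxel complex angle of the weights is the
#' phase-delay map in radians on [0, 2pi), encoding relative time lags
#' between voxels. The arbitrary global phase is rotated so the gray-voxel
#' mean weight is real and positive, unless an `anchor` score series is
#' supplied, in which case phase zero is aligned to the anchor's troughs
#' (e.g. PPG-amplitude drops).
#'
#' @inheritParams fit_pca
#' @param anchor Optional reference [feature_series()] or numeric series on
#'   the concatenated frame grid used to fix the global phase.
#' @return A `complex_component`: complex `weights` (unit norm), complex
#'   `scores`, `phase_delay_map` (radians in [0, 2pi)),
#'   `explained_variance_ratio`.
#' @export
fit_cpca <- function(data, zscore_runs = TRUE, solver = c("exact", "randomized"),
                     anchor = NULL) {
  solver <- match.arg(solver)
  cr <- concat_runs(data, zscore_runs)
  Xc <- apply(cr$X, 2, analytic_signal)
  s <- if (solver == "exact") svd(Xc, nu = 1, nv = 1) else randomized_svd(Xc, 1)
  w <- s$v[, 1]
  scores <- (Xc %*% w)[, 1]
  if (!is.null(anchor)) {
    av <- if (inherits(anchor, "feature_series")) anchor$values else anchor
    # align phase 0 of the scores with drops (minima) of the anchor series
    rot <- -Arg(sum(exp(1i * Arg(scores)) * (-av)))
  } else {
    ref <- if (!is.null(cr$tissue) && any(cr$tissue == "gray")) {
      mean(w[cr$tissue == "gray"])
    } else {
      mean(w)
    }
    rot <- -Arg(ref)
  }
  w <- w * exp(1i * rot)
  scores <- scores * exp(1i * rot)
  total_var <- sum(Mod(Xc)^2)
  structure(list(weights = w, scores = scores,
                 phase_delay_map = Arg(w) %% (2 * pi),
                 explained_variance_ratio = s$d[1]^2 / total_var,
                 tr_s = cr$tr_s, tissue_label = cr$tissue),
            class = "complex_component")
}

#' Phase-binned temporal reconstruction ("movie") of a complex component
#'
#' Frames are assigned to `n_bins` equally spaced bins by the temporal
#' phase of the component scores; the real part of the rank-1 complex
#' reconstruction (the component's voxel-space projection) is averaged
#' within each bin. The result is an `n_bins`-volume movie of the
#' component's spatiotemporal evolution, ordered by bin-center phase.
#'
#' @param comp A `complex_component` from [fit_cpca()].
#' @param n_bins Number of phase bins (default 30).
#' @return List: `maps` (n_bins x voxels matrix), `bin_centers` (radians),
#'   `bin_counts`.
#' @export
reconstruct_movie <- function(comp, n_bins = 30) {
  stopifnot(inherits(comp, "complex_component"))
  if (n_bins < 2) stop("`n_bins` must be at least 2")
  ph <- Arg(comp$scores) %% (2 * pi)
  edges <- seq(0, 2 * pi, length.out = n_bins + 1)
  bin <- findInterval(ph, edges, rightmost.closed = TRUE)
  counts <- tabulate(bin, n_bins)
  if (any(counts == 0)) {
    stop(sprintf("empty phase bins: %s (occupancy: %s); reduce `n_bins`",
                 paste(which(counts == 0), collapse = ","),
                 paste(counts, collapse = ",")))
  }
  recon <- Re(outer(comp$scores, Conj(comp$weights)))
  maps <- matrix(0, n_bins, length(comp$weights))
  for (b in seq_len(n_bins)) {
    maps[b, ] <- colMeans(recon[bin == b, , drop = FALSE])
  }
  list(maps = maps, bin_centers = (edges[-1] + edges[-(n_bins + 1)]) / 2,
       bin_counts = counts)
}

#' @export
print.real_component <- function(x, ...) {
  cat(sprintf("<real_component> %d voxels, %d frames, EVR %.3f\n",
              length(x$weights), length(x$scores), x$explained_variance_ratio))
  invisible(x)
}

#' @export
print.complex_component <- function(x, ...) {
  cat(sprintf("<complex_component> %d voxels, %d frames, EVR %.3f\n",
              length(x$weights), length(x$scores), x$explained_variance_ratio))
  invisible(x)
}
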