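# Volume-wise monoexponential decay modeling of multi-echo fMRI
# (log-linear least squares for T2* and S0 per frame and voxel) and
# cardiac RETROICOR: Fourier regressors of cardiac phase evaluated at
# per-slice acquisition times, with max-R2 selection across slices.

#' Construct a multi-echo series container
#'
#' @param data Frames x echoes x voxels array.
#' @param echo_times_ms Echo times (ms), >= 2, strictly increasing.
#' @param tr_s Repetition time (s).
#' @param slice_of_voxel Optional per-voxel slice index.
#' @param slice_timing_s Optional per-slice acquisition offset (s).
#' @return A `multi_echo_series`.
#' @export
multi_echo_series <- function(data, echo_times_ms, tr_s, slice_of_voxel = NULL,
                              slice_timing_s = NULL) {
  if (length(dim(data)) != 3) stop("`data` must be frames x echoes x voxels")
  if (length(echo_times_ms) < 2) stop("need at least 2 echo times")
  if (any(echo_times_ms <= 0) || any(diff(echo_times_ms) <= 0)) {
    stop("echo times must be positive and strictly increasing")
  }
  if (dim(data)[2] != length(echo_times_ms)) {
    stop("second dimension must match the number of echoes")
  }
  structure(list(data = data, echo_times_ms = echo_times_ms, tr_s = tr_s,
                 slice_of_voxel = slice_of_voxel,
                 slice_timing_s = slice_timing_s),
            class = "multi_echo_series")
}

#' Volume-wise T2*/S0 from a log-linear monoexponential fit
#'
#' For each frame and voxel, ordinary least squares of `log(S)` on echo
#' time fits `S(TE) = S0 * exp(-TE / T2*)`: `T2* = -1/slope` and
#' `S0 = exp(intercept)`. Frames/voxels with any nonpositive echo sample
#' are excluded (`valid = FALSE`), as are nonphysical fits (slope >= 0).
#'
#' @param me A `multi_echo_series` (or list with the same fields).
#' @return A `decay_series`: `t2s_ms`, `s0` (frames x voxels), `valid`
#'   (logical frames x voxels).
#' @export
fit_decay <- function(me) {
  data <- me$data
  te <- me$echo_times_ms
  d <- dim(data)
  n <- d[1]; ne <- d[2]; nv <- d[3]
  flat <- matrix(aperm(data, c(2, 1, 3)), ne)   # echoes x (frames*voxels)
  ok <- colSums(flat > 0) == ne & colSums(is.finite(flat)) == ne
  logs <- log(pmax(flat, .Machine$double.xmin))
  tec <- te - mean(te)
  slope <- colSums(tec * logs) / sum(tec^2)
  intercept <- colMeans(logs) - slope * mean(te)
  valid <- ok & slope < 0
  t2s <- ifelse(valid, -1 / slope, NA_real_)
  s0 <- ifelse(valid, exp(intercept), NA_real_)
  structure(list(t2s_ms = matrix(t2s, n, nv), s0 = matrix(s0, n, nv),
                 valid = matrix(valid, n, nv), echo_times_ms = te),
            class = "decay_series")
}

#' Cardiac phase and RETROICOR Fourier regressors per slice
#'
#' Phase within each cardiac cycle is linear between consecutive systolic
#' peaks, `phi(t) = 2 pi (t - t_k) / (t_{k+1} - t_k)` for
#' `t in [t_k, t_{k+1})`. Regressors are `cos(m phi), sin(m phi)` for
#' `m = 1..order`, evaluated at each slice's acquisition times
#' (frame time + slice offset).
#'
#' @param beats A [beat_series()] spanning all requested times.
#' @param frame_times_s Frame acquisition times (s), before slice offset.
#' @param slice_timing_s Per-slice offsets (s); default a single slice at
#'   offset 0.
#' @param order Fourier expansion order M (default 2).
#' @return A `cardiac_phase`: `phase` (frames x slices, radians in
#'   [0, 2pi)), `regressors` (list per slice of frames x 2M matrices),
#'   `order`.
#' @export
cardiac_phase <- function(beats, frame_times_s, slice_timing_s = 0, order = 2) {
  tb <- beats$peak_times_s
  if (length(tb) < 2) stop("need at least 2 beats")
  n <- length(frame_times_s)
  phase <- matrix(0, n, length(slice_timing_s))
  regressors <- vector("list", length(slice_timing_s))
  for (s in seq_along(slice_timing_s)) {
    t <- frame_times_s + slice_timing_s[s]
    if (any(t < tb[1]) || any(t >= tb[length(tb)])) {
      stop("frame time outside the span of detected beats")
    }
    k <- findInterval(t, tb)
    ph <- 2 * pi * (t - tb[k]) / (tb[k + 1] - tb[k])
    phase[, s] <- ph
    reg <- matrix(0, n, 2 * order)
    for (m in seq_len(order)) {
      reg[, 2 * m - 1] <- cos(m * ph)
      reg[, 2 * m] <- sin(m * ph)
    }
    colnames(reg) <- as.vector(rbind(paste0("cos", seq_len(order)),
                                     paste0("sin", seq_len(order))))
    regressors[[s]] <- reg
  }
  structure(list(phase = phase, regressors = regressors, order = order,
                 slice_timing_s = slice_timing_s),
            class = "cardiac_phase")
}

#' Maximum explained variance across slice-specific cardiac regressors
#'
#' Regresses each voxel's series on every slice's RETROICOR regressor
#' matrix (with intercept) and returns the maximum R-squared across
#' slices. Constant voxel series get R2 = 0 with `degenerate = TRUE`.
#'
#' @param voxel_data Frames x voxels matrix.
#' @param phase A `cardiac_phase` with regressors for every slice.
#' @return List: `r2` (per-voxel max R2), `best_slice`, `degenerate`
#'   (logical per voxel).
#' @export
max_slice_r2 <- function(voxel_data, phase) {
  voxel_data <- as.matrix(voxel_data)
  nv <- ncol(voxel_data)
  Y <- sweep(voxel_data, 2, colMeans(voxel_data))
  tss <- colSums(Y^2)
  degenerate <- tss < 1e-24
  r2_all <- matrix(0, length(phase$regressors), nv)
  for (s in seq_along(phase$regressors)) {
    X <- cbind(1, phase$regressors[[s]])
    Q <- qr.Q(qr(X))
    fitted <- Q %*% crossprod(Q, Y)
    rss <- colSums((Y - fitted)^2)
    r2_all[s, ] <- ifelse(degenerate, 0, 1 - rss / pmax(tss, 1e-24))
  }
  list(r2 = apply(r2_all, 2, max),
       best_slice = apply(r2_all, 2, which.max),
       degenerate = degenerate)
}

#' @export
print.decay_series <- function(x, ...) {
  cat(sprintf("<decay_series> %d frames x %d voxels, %.1f%% valid fits\n",
              nrow(x$t2s_ms), ncol(x$t2s_ms), 100 * mean(x$valid)))
  invisible(x)
}
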