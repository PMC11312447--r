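# Multi-set canonical correlation analysis of all signals and their lags:
# each signal contributes a "set" of three spline-weighted lagged copies
# (a distributed-lag basis over 0-10 s); the SUMCOR-style generalized
# eigenproblem finds per-set weights maximizing the average pairwise
# correlation of the canonical variates; inference is by subject-block
# permutation that destroys cross-signal coupling while preserving each
# signal's autocorrelation.

#' Build a distributed-lag predictor set for one signal
#'
#' Samples a natural cubic spline basis (default 3 functions: boundary
#' knots at the window edges, one interior knot at the midpoint) on the
#' integer-frame lag grid covering `window_s`, and forms column
#' `k = sum_l B_k(l) x(t - l)` with edge padding by the boundary value.
#'
#' @param feature A [feature_series()] or numeric vector.
#' @param window_s Lag window `(min, max)` in seconds, default `c(0, 10)`.
#' @param n_splines Number of basis functions (default 3).
#' @param tr_s Frame duration; taken from `feature` when it is a
#'   [feature_series()].
#' @return A `lagged_predictor_set`: `columns` (frames x n_splines),
#'   `basis` (lag grid x n_splines), `lag_grid_s`, `name`.
#' @export
build_lagged_set <- function(feature, window_s = c(0, 10), n_splines = 3,
                             tr_s = NULL) {
  x <- if (inherits(feature, "feature_series")) feature$values else as.numeric(feature)
  if (is.null(tr_s)) {
    tr_s <- if (inherits(feature, "feature_series")) feature$tr_s else 1
  }
  n <- length(x)
  lag_frames <- seq(floor(window_s[1] / tr_s), ceiling(window_s[2] / tr_s))
  if (length(lag_frames) >= n) stop("lag window longer than the series")
  lag_s <- lag_frames * tr_s
  if (n_splines < 2) stop("`n_splines` must be >= 2")
  inner <- if (n_splines > 2) {
    seq(window_s[1], window_s[2], length.out = n_splines)[2:(n_splines - 1)]
  } else {
    NULL
  }
  B <- splines::ns(lag_s, knots = inner, Boundary.knots = window_s,
                   intercept = TRUE)
  B <- unclass(B)[, seq_len(n_splines), drop = FALSE]
  cols <- matrix(0, n, n_splines)
  for (j in seq_along(lag_frames)) {
    l <- lag_frames[j]
    shifted <- x[pmin(pmax(seq_len(n) - l, 1), n)]
    cols <- cols + outer(shifted, B[j, ])
  }
  structure(list(columns = cols, basis = B, lag_grid_s = lag_s,
                 window_s = window_s,
                 name = x_name(feature)),
            class = "lagged_predictor_set")
}

set_matrix <- function(s) {
  if (inherits(s, "lagged_predictor_set")) s$columns else as.matrix(s)
}

#' Fit the first multi-set canonical component (SUMCOR)
#'
#' Solves the sum-of-correlations MCCA as the generalized eigenproblem
#' `C w = lambda D w`, where `C` is the covariance of all concatenated set
#' columns and `D` its block-diagonal within-set part (with a small ridge
#' for conditioning). The leading eigenvector gives per-set weights; each
#' set's canonical variate is scaled to unit variance, and the achieved
#' mean pairwise correlation of the variates is reported.
#'
#' @param sets Named list of `lagged_predictor_set`s or frames x d
#'   matrices (equal frame counts).
#' @param ridge_frac Ridge added to each within-set block, as a fraction
#'   of its mean diagonal (default 1e-6). 0 demands full-rank blocks.
#' @return An `mcca_solution`: `weights` (per-set list), `variates`
#'   (frames x k, unit variance), `pairwise_r` (k x k),
#'   `mean_pairwise_r`.
#' @export
fit_mcca <- function(sets, ridge_frac = 1e-6) {
  if (length(sets) < 2) stop("need at least 2 sets")
  mats <- lapply(sets, set_matrix)
  n <- nrow(mats[[1]])
  for (m in mats) if (nrow(m) != n) stop("sets must share the frame count")
  mats <- lapply(mats, function(m) sweep(m, 2, colMeans(m)))
  dims <- vapply(mats, ncol, 0L)
  X <- do.call(cbind, mats)
  C <- crossprod(X) / (n - 1)
  D <- matrix(0, ncol(X), ncol(X))
  off <- cumsum(c(0, dims))
  for (i in seq_along(mats)) {
    ix <- (off[i] + 1):off[i + 1]
    blk <- C[ix, ix, drop = FALSE]
    if (ridge_frac == 0 && rcond(blk) < 1e-12) {
      stop("rank-deficient within-set covariance; use `ridge_frac` > 0")
    }
    # ridge proportional to each column's own variance keeps the solution
    # exactly invariant to per-column rescaling
    D[ix, ix] <- blk + diag(ridge_frac * diag(blk), length(ix))
  }
  L <- tryCatch(chol(D), error = function(e) {
    stop("within-set covariance not positive definite; increase `ridge_frac`")
  })
  M <- backsolve(L, t(backsolve(L, C, transpose = TRUE)), transpose = TRUE)
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE)
  w <- backsolve(L, ev$vectors[, 1])
  weights <- vector("list", length(mats))
  variates <- matrix(0, n, length(mats))
  for (i in seq_along(mats)) {
    ix <- (off[i] + 1):off[i + 1]
    wi <- w[ix]
    zi <- as.numeric(mats[[i]] %*% wi)
    s <- stats::sd(zi)
    if (s < 1e-12) s <- 1
    weights[[i]] <- wi / s
    variates[, i] <- zi / s
  }
  names(weights) <- names(sets)
  colnames(variates) <- names(sets)
  R <- stats::cor(variates)
  structure(list(weights = weights, variates = variates, pairwise_r = R,
                 mean_pairwise_r = mean(R[upper.tri(R)]),
                 eigenvalue = ev$values[1]),
            class = "mcca_solution")
}

#' Subject-block permutation test of the mean pairwise correlation
#'
#' The observed statistic is the mean pairwise correlation of the first
#' canonical component fit on subject-wise temporal concatenation. Under
#' each permutation the subject assignment of every signal is shuffled
#' independently (signal A from subject 1 may be paired with signal B from
#' subject 7), removing cross-signal coupling while keeping each signal's
#' autocorrelation intact, and the model is refit. The p-value uses the
#' add-one correction `(1 + #{null >= obs}) / (n_perm + 1)`.
#'
#' @param subject_sets List over subjects; each element a named list of
#'   `lagged_predictor_set`s (same signals, same frame count everywhere).
#' @param n_perm Number of permutations (default 1000).
#' @param seed RNG seed.
#' @param ridge_frac Passed to [fit_mcca()].
#' @return An `mcca_solution` augmented with `null_r`, `p_value`,
#'   `n_perm`.
#' @export
permutation_test <- function(subject_sets, n_perm = 1000, seed = 1,
                             ridge_frac = 1e-6) {
  ns <- length(subject_sets)
  if (ns < 3) stop("need at least 3 subjects for a nontrivial permutation test")
  sig_names <- names(subject_sets[[1]])
  blocks <- lapply(sig_names, function(sn) {
    lapply(subject_sets, function(ss) set_matrix(ss[[sn]]))
  })
  names(blocks) <- sig_names
  nf <- nrow(blocks[[1]][[1]])
  for (b in blocks) for (m in b) {
    if (nrow(m) != nf) stop("all subjects must share the frame count")
  }
  concat <- function(perm_list) {
    sets <- lapply(sig_names, function(sn) {
      do.call(rbind, blocks[[sn]][perm_list[[sn]]])
    })
    names(sets) <- sig_names
    sets
  }
  identity_perm <- stats::setNames(rep(list(seq_len(ns)), length(sig_names)),
                                   sig_names)
  obs_fit <- fit_mcca(concat(identity_perm), ridge_frac)
  set.seed(seed)
  null_r <- vapply(seq_len(n_perm), function(i) {
    perm <- stats::setNames(lapply(sig_names, function(sn) sample(ns)),
                            sig_names)
    fit_mcca(concat(perm), ridge_frac)$mean_pairwise_r
  }, numeric(1))
  obs_fit$null_r <- null_r
  obs_fit$p_value <- (1 + sum(null_r >= obs_fit$mean_pairwise_r)) / (n_perm + 1)
  obs_fit$n_perm <- n_perm
  obs_fit
}

#' @export
print.mcca_solution <- function(x, ...) {
  cat(sprintf("<mcca_solution> %d sets, mean pairwise r = %.3f%s\n",
              ncol(x$variates), x$mean_pairwise_r,
              if (!is.null(x$p_value)) sprintf(", p = %.4g (%d perms)",
                                               x$p_value, x$n_perm) else ""))
  invisible(x)
}
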