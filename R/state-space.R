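#' Stationary interval grid
#'
#' Partition of a record into I contiguous, nonoverlapping intervals of J
#' samples each, the minimal blocks on which the process is treated as
#' second-order stationary. Trailing samples that do not fill an interval
#' are dropped.
#'
#' @param n_samples record length in samples.
#' @param J samples per interval.
#' @return An object of class `"interval_grid"`: list with `J`, `I`,
#'   `centers` (1-based center sample index per interval) and `n_samples`.
#' @export
interval_grid <- function(n_samples, J) {
  J <- as.integer(J); n_samples <- as.integer(n_samples)
  if (J < 1L) stop("`J` must be >= 1 sample")
  I <- n_samples %/% J
  if (I < 2L) stop("record too short: need at least 2 intervals of J samples")
  centers <- (seq_len(I) - 1L) * J + as.integer(ceiling((J + 1) / 2))
  structure(list(J = J, I = I, centers = centers, n_samples = n_samples),
            class = "interval_grid")
}

#' Per-interval spectral observations
#'
#' Evaluates the spline-kerneled chirplet transform at each stationary
#' interval's center time, giving the complex observation matrix
#' `Y[s, i]` (frequency line s, interval i) that the per-line state-space
#' model treats as noisy measurements of the spectral increments.
#'
#' @param ts a [time_series()].
#' @param grid an [interval_grid()]; must fit the record.
#' @param kernel a [spline_if_kernel()] or `NULL` (plain short-time
#'   transform).
#' @param window_sd,n_lines see [sct()].
#' @return An object of class `"spectral_obs"`: list with `Y`
#'   (S x I complex), `freqs` (Hz), `times` (interval centers, s), `grid`.
#' @export
build_observations <- function(ts, grid, kernel = NULL, window_sd = 0.5,
                               n_lines = 256) {
  stopifnot(inherits(ts, "time_series"), inherits(grid, "interval_grid"))
  if (grid$n_samples > length(ts$values) ||
      grid$I * grid$J > length(ts$values))
    stop("interval grid does not fit the record")
  x <- sct_at(ts, kernel, window_sd, grid$centers, n_lines)
  structure(list(Y = x$coeffs, freqs = x$freqs, times = x$times,
                 grid = grid),
            class = "spectral_obs")
}

#' @export
print.spectral_obs <- function(x, ...) {
  cat(sprintf("<spectral_obs> S = %d frequency lines x I = %d intervals (J = %d samples)\n",
              nrow(x$Y), ncol(x$Y), x$grid$J))
  invisible(x)
}

#' Model parameters of the per-line state-space model
#'
#' @param sigma_eps2 shared observation-noise variance (> 0).
#' @param sigma_v2 per-line innovation variances of the random-walk
#'   continuity prior (length S, > 0).
#' @param z0 initial spectral increments (complex, length S).
#' @param sigma02 initial-state variances (length S, >= 0).
#' @return An object of class `"model_params"`. Variances are floored at
#'   1e-12 to keep the Kalman gain defined.
#' @export
model_params <- function(sigma_eps2, sigma_v2, z0, sigma02) {
  S <- max(length(sigma_v2), length(z0), length(sigma02))
  if (length(sigma_v2) == 1L) sigma_v2 <- rep(sigma_v2, S)
  if (length(z0) == 1L) z0 <- rep(z0, S)
  if (length(sigma02) == 1L) sigma02 <- rep(sigma02, S)
  if (length(z0) != S || length(sigma02) != S || length(sigma_v2) != S)
    stop("`sigma_v2`, `z0`, `sigma02` must share length S")
  if (!is.finite(sigma_eps2) || sigma_eps2 <= 0)
    stop("`sigma_eps2` must be a positive number")
  structure(list(sigma_eps2 = max(sigma_eps2, .var_floor),
                 sigma_v2 = pmax(as.numeric(sigma_v2), .var_floor),
                 z0 = as.complex(z0),
                 sigma02 = pmax(as.numeric(sigma02), 0)),
            class = "model_params")
}

.var_floor <- 1e-12

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("<model_params> S = %d lines; sigma_eps2 = %.4g; sigma_v2 in [%.4g, %.4g]\n",
              length(x$sigma_v2), x$sigma_eps2,
              min(x$sigma_v2), max(x$sigma_v2)))
  invisible(x)
}

# --- matrix-form recursions (vectorized over frequency lines) -------------

# Forward complex Kalman filter. Y: S x I complex. Returns matrices with
# column j holding interval i = j (pred, gain) or i = j - 1 (filt: the first
# column is the i = 0 prior state).
ss_filter <- function(Y, params) {
  S <- nrow(Y); I <- ncol(Y)
  filt_mean <- matrix(0i, S, I + 1L); filt_var <- matrix(0, S, I + 1L)
  pred_mean <- matrix(0i, S, I); pred_var <- matrix(0, S, I)
  gain <- matrix(0, S, I)
  filt_mean[, 1L] <- params$z0
  filt_var[, 1L] <- params$sigma02
  for (i in seq_len(I)) {
    pm <- filt_mean[, i]                    # predict: random-walk mean
    pv <- filt_var[, i] + params$sigma_v2
    C <- pv / (params$sigma_eps2 + pv)
    pred_mean[, i] <- pm; pred_var[, i] <- pv; gain[, i] <- C
    filt_mean[, i + 1L] <- pm + C * (Y[, i] - pm)
    filt_var[, i + 1L] <- (1 - C) * pv
  }
  list(filt_mean = filt_mean, filt_var = filt_var,
       pred_mean = pred_mean, pred_var = pred_var, gain = gain,
       S = S, I = I)
}

# Fixed-interval (RTS) smoother over a filtered pass; smooths back to i = 0.
ss_smooth <- function(filt) {
  S <- filt$S; I <- filt$I
  sm_mean <- filt$filt_mean; sm_var <- filt$filt_var
  A <- matrix(0, S, I)                       # A[, j] = A_{i = j - 1}
  if (I >= 1L) for (i in I:1L) {
    pv <- filt$pred_var[, i]
    a <- ifelse(pv > 0, filt$filt_var[, i] / pv, 0)
    A[, i] <- a
    sm_mean[, i] <- filt$filt_mean[, i] +
      a * (sm_mean[, i + 1L] - filt$pred_mean[, i])
    sm_var[, i] <- filt$filt_var[, i] +
      a^2 * (sm_var[, i + 1L] - filt$pred_var[, i])
  }
  lag1 <- A * sm_var[, -1L, drop = FALSE]    # cov(i, i+1 | I), i = 0..I-1
  list(sm_mean = sm_mean, sm_var = pmax(sm_var, 0), A = A, lag1 = lag1)
}

# --- per-line operation surface -------------------------------------------

#' Complex Kalman filter for one frequency line
#'
#' Forward recursion for the random-walk observation model
#' `Y_i = DeltaZ_i + eps_i`, `DeltaZ_i = DeltaZ_{i-1} + v_i`: predict
#' `DeltaZ_{i|i-1} = DeltaZ_{i-1|i-1}`,
#' `sigma2_{i|i-1} = sigma2_{i-1|i-1} + sigma_v2`; gain
#' `C_i = sigma2_{i|i-1} / (sigma_eps2 + sigma2_{i|i-1})`; update
#' `DeltaZ_{i|i} = DeltaZ_{i|i-1} + C_i (Y_i - DeltaZ_{i|i-1})`,
#' `sigma2_{i|i} = (1 - C_i) sigma2_{i|i-1}`.
#'
#' @param y_line complex observations for one line (length I).
#' @param params a [model_params()].
#' @param s line index into `params` (default 1).
#' @return list with vectors `pred_mean`, `pred_var`, `filt_mean`,
#'   `filt_var`, `gain` (each length I) and scalars `filt_mean0`,
#'   `filt_var0` for the i = 0 prior state.
#' @export
kalman_filter_line <- function(y_line, params, s = 1L) {
  stopifnot(inherits(params, "model_params"), length(y_line) >= 1L)
  p1 <- model_params(params$sigma_eps2, params$sigma_v2[s],
                     params$z0[s], params$sigma02[s])
  f <- ss_filter(matrix(as.complex(y_line), nrow = 1L), p1)
  list(pred_mean = f$pred_mean[1L, ], pred_var = f$pred_var[1L, ],
       filt_mean = f$filt_mean[1L, -1L], filt_var = f$filt_var[1L, -1L],
       gain = f$gain[1L, ],
       filt_mean0 = f$filt_mean[1L, 1L], filt_var0 = f$filt_var[1L, 1L],
       .mat = f)
}

#' Fixed-interval smoother for one filtered line
#'
#' Backward recursion `A_i = sigma2_{i|i} / sigma2_{i+1|i}`,
#' `DeltaZ_{i|I} = DeltaZ_{i|i} + A_i (DeltaZ_{i+1|I} - DeltaZ_{i+1|i})`,
#' `sigma2_{i|I} = sigma2_{i|i} + A_i^2 (sigma2_{i+1|I} - sigma2_{i+1|i})`,
#' initialized at i = I with the filtered values and run back to the i = 0
#' initial state. A zero predicted variance gives `A_i = 0` (no information
#' flows backward through a degenerate step).
#'
#' @param filtered output of [kalman_filter_line()].
#' @return list with vectors `sm_mean`, `sm_var` (length I), `A` (length I,
#'   `A[i]` being the gain from state i-1), scalars `sm_mean0`, `sm_var0`.
#' @export
smooth_line <- function(filtered) {
  sm <- ss_smooth(filtered$.mat)
  list(sm_mean = sm$sm_mean[1L, -1L], sm_var = sm$sm_var[1L, -1L],
       A = sm$A[1L, ], sm_mean0 = sm$sm_mean[1L, 1L],
       sm_var0 = sm$sm_var[1L, 1L], .sm = sm, .mat = filtered$.mat)
}

#' Lag-one smoothed covariances for one line
#'
#' `sigma_{i,i+1|I} = A_i * sigma2_{i+1|I}` for i = 0..I-1, the only
#' cross-covariances the EM sufficient statistics require. The general
#' recursion `sigma_{i,u|I} = A_i * sigma_{i+1,u|I}` is available through
#' [cov_between()].
#'
#' @param smoothed output of [smooth_line()].
#' @return numeric vector of length I; element i is cov(state i-1, state i).
#' @export
lag_covariances <- function(smoothed) {
  drop(smoothed$.sm$lag1)
}

#' Smoothed covariance between two states of one line
#'
#' Applies `sigma_{i,u|I} = A_i sigma_{i+1,u|I}` down from `u`.
#'
#' @param smoothed output of [smooth_line()].
#' @param i,u state indices with `0 <= i <= u <= I`.
#' @return the smoothed covariance (real).
#' @export
cov_between <- function(smoothed, i, u) {
  stopifnot(i >= 0, u >= i)
  sm_var <- c(smoothed$sm_var0, smoothed$sm_var)
  g <- sm_var[u + 1L]
  if (u > i) for (k in (u - 1L):i) g <- smoothed$A[k + 1L] * g
  g
}
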