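#' Spline instantaneous-frequency kernel
#'
#' A cubic-spline model kappa(t) of instantaneous frequency in Hz over a
#' record, the kernel of the frequency-rotate and frequency-shift operators
#' of the spline-kerneled chirplet transform. Outside the knot span kappa is
#' held at its boundary value.
#'
#' @param knots strictly increasing knot times in seconds (>= 2).
#' @param coef spline coefficients in the cubic B-spline basis over `knots`
#'   (length `length(knots) + 2`).
#' @param residual_rms RMS residual of the fit that produced the kernel
#'   (informational).
#' @return An object of class `"spline_if_kernel"`.
#' @seealso [fit_spline_kernel()], [kernel_eval()], [sct()]
#' @export
spline_if_kernel <- function(knots, coef, residual_rms = NA_real_) {
  knots <- as.numeric(knots)
  if (length(knots) < 2L || any(diff(knots) <= 0))
    stop("`knots` must be >= 2 strictly increasing times")
  if (length(coef) != length(knots) + 2L)
    stop("`coef` must have length(knots) + 2 elements")
  if (!all(is.finite(coef))) stop("spline coefficients must be finite")
  structure(list(knots = knots, coef = as.numeric(coef),
                 residual_rms = residual_rms),
            class = "spline_if_kernel")
}

#' Constant-frequency kernel
#' @param f0 frequency in Hz.
#' @param from,to knot span in seconds.
#' @return a [spline_if_kernel()] with kappa(t) = f0.
#' @export
constant_kernel <- function(f0, from, to) {
  k <- spline_if_kernel(c(from, to), rep(0, 4))
  # a constant is in the cubic spline space: solve for its coefficients
  tt <- seq(from, to, length.out = 8)
  B <- kernel_basis(k$knots, tt)
  k$coef <- stats::lm.fit(B, rep(as.numeric(f0), length(tt)))$coefficients
  k$coef[is.na(k$coef)] <- 0
  k$residual_rms <- 0
  k
}

#' @export
print.spline_if_kernel <- function(x, ...) {
  f <- kernel_eval(x, x$knots)
  cat(sprintf(
    "<spline_if_kernel> %d knots on [%.3g, %.3g] s, kappa in [%.4g, %.4g] Hz\n",
    length(x$knots), min(x$knots), max(x$knots), min(f), max(f)))
  if (is.finite(x$residual_rms))
    cat(sprintf("  fit residual RMS: %.4g Hz\n", x$residual_rms))
  invisible(x)
}

# cubic B-spline design matrix over the augmented knot vector
kernel_basis <- function(knots, t) {
  aug <- c(rep(knots[1L], 3L), knots, rep(knots[length(knots)], 3L))
  t <- pmin(pmax(t, knots[1L]), knots[length(knots)])
  splines::splineDesign(aug, t, ord = 4L)
}

#' Evaluate a spline IF kernel
#' @param kernel a [spline_if_kernel()].
#' @param t times in seconds (clamped to the knot span).
#' @return kappa(t) in Hz.
#' @export
kernel_eval <- function(kernel, t) {
  stopifnot(inherits(kernel, "spline_if_kernel"))
  drop(kernel_basis(kernel$knots, t) %*% kernel$coef)
}

# cumulative phase integral of kappa over a uniform sample grid (cycles)
kernel_phase <- function(kernel, t) {
  f <- kernel_eval(kernel, t)
  n <- length(t)
  dt <- diff(t)
  c(0, cumsum(dt * (f[-n] + f[-1L]) / 2))
}

#' Least-squares cubic spline fit to a ridge track
#'
#' Fits kappa(t) through an extracted (time, frequency) track with `n_knots`
#' equispaced knots spanning the track.
#'
#' @param track two-column matrix or data frame (time_s, freq_hz).
#' @param n_knots number of knots including the endpoints (>= 2).
#' @return a [spline_if_kernel()] with `residual_rms` set.
#' @export
fit_spline_kernel <- function(track, n_knots = 8) {
  track <- as.matrix(track)
  stopifnot(ncol(track) >= 2, n_knots >= 2)
  t <- as.numeric(track[, 1L]); y <- as.numeric(track[, 2L])
  if (length(unique(t)) < 2L)
    stop("degenerate track: all observations at one time")
  if (length(unique(t)) < n_knots)
    stop("track must cover at least `n_knots` distinct times")
  knots <- seq(min(t), max(t), length.out = n_knots)
  B <- kernel_basis(knots, t)
  fit <- stats::lm.fit(B, y)
  co <- fit$coefficients
  co[is.na(co)] <- 0
  res <- y - drop(B %*% co)
  spline_if_kernel(knots, co, residual_rms = sqrt(mean(res^2)))
}

#' Short-time Fourier transform (Gaussian window)
#'
#' Gaussian-windowed short-time transform of the analytic signal on
#' `n_lines` equispaced frequency lines spanning `[0, fs/2]`, one column per
#' hop position. This is exactly [sct()] with a zero kernel: the chirplet
#' rotate/shift operators vanish and the transforms agree bit for bit.
#'
#' @param ts a [time_series()].
#' @param window_sd Gaussian window standard deviation in seconds (the
#'   window is truncated at +/- 4 sd).
#' @param hop hop between successive columns, in samples.
#' @param n_lines number of frequency lines (>= 2).
#' @return a [tfr()].
#' @export
stft <- function(ts, window_sd = 0.5, hop = 10, n_lines = 256) {
  sct(ts, kernel = NULL, window_sd = window_sd, hop = hop, n_lines = n_lines)
}

#' Spline-kerneled chirplet transform
#'
#' Demodulated short-time analysis: the analytic signal is multiplied by the
#' frequency-rotate operator `exp(-j*2*pi*integral_0^t kappa(u) du)` and,
#' per column at center `t0`, by the frequency-shift operator
#' `exp(+j*2*pi*kappa(t0)*t)` before Gaussian-windowed Fourier analysis.
#' A component whose instantaneous frequency follows `kappa` appears as a
#' concentrated ridge at `kappa(t0)`; with `kernel = NULL` (kappa identically
#' zero) the transform reduces exactly to [stft()].
#'
#' @inheritParams stft
#' @param kernel a [spline_if_kernel()], or `NULL` for the zero kernel.
#' @return a [tfr()] whose rows are `n_lines` equispaced frequencies on
#'   `[0, fs/2]`.
#' @export
sct <- function(ts, kernel = NULL, window_sd = 0.5, hop = 10, n_lines = 256) {
  stopifnot(inherits(ts, "time_series"))
  if (window_sd <= 0) stop("`window_sd` must be positive")
  if (hop < 1) stop("`hop` must be >= 1 sample")
  if (n_lines < 2) stop("`n_lines` must be >= 2")
  centers <- seq(1L, length(ts$values), by = as.integer(hop))
  sct_at(ts, kernel, window_sd, centers, n_lines)
}

# shared SCT engine: columns at explicit sample-index centers
sct_at <- function(ts, kernel, window_sd, centers, n_lines) {
  x <- ts$values
  n <- length(x)
  fs <- ts$fs
  R <- as.integer(round(4 * window_sd * fs))
  L <- 2L * R + 1L
  if (n < L)
    stop(sprintf(
      "signal too short for the window: need >= %d samples (8 window sd), got %d",
      L, n))
  t_abs <- ts_times(ts)
  z <- analytic_signal(x)
  if (is.null(kernel)) {
    kap <- numeric(n)
    phi <- numeric(n)
  } else {
    stopifnot(inherits(kernel, "spline_if_kernel"))
    kap <- kernel_eval(kernel, t_abs)
    if (any(kap > fs / 2))
      warning("kernel exceeds the Nyquist frequency fs/2: aliasing expected")
    phi <- kernel_phase(kernel, t_abs)
  }
  d <- z * exp(-2i * pi * phi)                    # frequency-rotate
  freqs <- seq(0, fs / 2, length.out = n_lines)
  tau <- (-R:R) / fs
  w <- exp(-tau^2 / (2 * window_sd^2))
  # E[f, l] = exp(-j 2 pi f tau_l): shared across columns
  E <- exp(-2i * pi * outer(freqs, tau))
  coeffs <- matrix(0i, n_lines, length(centers))
  for (j in seq_along(centers)) {
    c0 <- centers[j]
    idx <- (c0 - R):(c0 + R)
    keep <- idx >= 1L & idx <= n
    g <- complex(length.out = L)
    # frequency-shift by kappa(t0) using absolute time, then window
    g[keep] <- d[idx[keep]] *
      exp(2i * pi * kap[c0] * t_abs[idx[keep]]) * w[keep]
    # exp(-j 2 pi f t) = exp(-j 2 pi f t0) * exp(-j 2 pi f tau)
    coeffs[, j] <- exp(-2i * pi * freqs * t_abs[c0]) * drop(E %*% g)
  }
  tfr(times = t_abs[centers], freqs = freqs, coeffs = coeffs)
}

#' Maximum-energy ridge by dynamic programming
#'
#' Extracts one frequency per column maximizing
#' `sum(|coeff|) - jump_penalty * sum(|delta bin|)` over all paths, by exact
#' dynamic programming with a linear per-bin frequency-jump cost. With
#' `jump_penalty = 0` this reduces to the per-column argmax.
#'
#' @param x a [tfr()] with nonzero energy.
#' @param jump_penalty cost per bin of frequency jump between adjacent
#'   columns; the default is twice the frequency bin width, a light
#'   smoothness prior on the instantaneous-frequency track. Pass a number
#'   to override (0 disables the coupling entirely).
#' @return data frame with columns `time_s`, `freq_hz`, `bin`.
#' @export
extract_ridge <- function(x, jump_penalty = NULL) {
  stopifnot(inherits(x, "tfr"))
  A <- Mod(x$coeffs)
  if (all(A == 0)) stop("all-zero TFR: no ridge to extract")
  S <- nrow(A); I <- ncol(A)
  if (is.null(jump_penalty)) jump_penalty <-
    2 * (if (length(x$freqs) > 1) diff(x$freqs[1:2]) else 1)
  lam <- as.numeric(jump_penalty)
  ptr <- matrix(0L, S, I)
  score <- A[, 1L]
  if (I > 1L) for (i in 2:I) {
    # distance transform of `score` under linear cost lam*|ds|
    best <- score; arg <- seq_len(S)
    if (S > 1L) {
      for (s in 2:S) if (best[s - 1L] - lam > best[s]) {
        best[s] <- best[s - 1L] - lam; arg[s] <- arg[s - 1L]
      }
      for (s in (S - 1L):1L) if (best[s + 1L] - lam > best[s]) {
        best[s] <- best[s + 1L] - lam; arg[s] <- arg[s + 1L]
      }
    }
    ptr[, i] <- arg
    score <- A[, i] + best
  }
  path <- integer(I)
  path[I] <- which.max(score)
  if (I > 1L) for (i in I:2) path[i - 1L] <- ptr[path[i], i]
  data.frame(time_s = x$times, freq_hz = x$freqs[path], bin = path)
}

#' Iteratively refined spline-kerneled chirplet transform
#'
#' Standard parameterized time-frequency refinement loop: STFT, ridge
#' extraction, spline fit of the ridge, SCT under the fitted kernel, and
#' repeat. The ridge of each SCT estimates the instantaneous frequency in
#' absolute Hz, so refitting converges once the kernel tracks the signal.
#'
#' @param ts a [time_series()].
#' @param n_iter number of refinement iterations (>= 1).
#' @param window_sd,hop,n_lines see [sct()].
#' @param n_knots spline knots for the kernel fit, see [fit_spline_kernel()].
#' @param jump_penalty see [extract_ridge()].
#' @return list with elements `kernel` (final [spline_if_kernel()]), `tfr`
#'   (final SCT), `ridge` (final ridge track) and `rms` (per-iteration RMS
#'   between the extracted ridge and the previous kernel, a convergence
#'   diagnostic).
#' @export
iterate_sct <- function(ts, n_iter = 3, window_sd = 0.5, hop = 10,
                        n_lines = 256, n_knots = 8, jump_penalty = NULL) {
  stopifnot(n_iter >= 1)
  cur <- stft(ts, window_sd = window_sd, hop = hop, n_lines = n_lines)
  ridge <- extract_ridge(cur, jump_penalty)
  rms <- numeric(n_iter)
  kernel <- NULL
  for (it in seq_len(n_iter)) {
    kernel <- fit_spline_kernel(ridge[, c("time_s", "freq_hz")], n_knots)
    cur <- sct(ts, kernel, window_sd = window_sd, hop = hop,
               n_lines = n_lines)
    ridge <- extract_ridge(cur, jump_penalty)
    rms[it] <- sqrt(mean((ridge$freq_hz -
                            kernel_eval(kernel, ridge$time_s))^2))
  }
  list(kernel = kernel, tfr = cur, ridge = ridge, rms = rms)
}
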