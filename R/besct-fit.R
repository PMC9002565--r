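#' Fit a Bayesian-embedded spline-kerneled chirplet spectrogram
#'
#' The package's central model fit. The record is first analyzed by an
#' iteratively refined spline-kerneled chirplet transform ([iterate_sct()]),
#' whose kernel demodulates the dominant nonlinear frequency law. The SCT
#' coefficients on a grid of stationary intervals are then treated as noisy
#' observations of latent spectral increments linked across intervals by a
#' complex random-walk continuity prior; per-frequency-line Kalman filtering
#' and fixed-interval smoothing give the joint Gaussian posterior, and the
#' observation and innovation variances are estimated by an EM algorithm
#' with gamma priors on the precisions ([run_em()]). The fitted surface
#' (smoothed posterior means) is the empirical-Bayes denoised spectrogram.
#'
#' @param x a [time_series()], or a numeric vector (then `fs` is required).
#' @param fs sampling rate in Hz when `x` is a bare vector.
#' @param window_sd,n_lines,n_knots,jump_penalty transform settings, see
#'   [sct()], [fit_spline_kernel()], [extract_ridge()].
#' @param hop hop in samples between transform columns; also the stationary
#'   interval length J, so each interval contributes one column.
#' @param n_iter kernel refinement iterations, see [iterate_sct()].
#' @param em an [em_config()].
#' @param kernel optionally a fixed [spline_if_kernel()]; skips refinement.
#' @return An object of class `"besct"`: list with `kernel`, `sct`
#'   (raw SCT [tfr()]), `obs` ([build_observations()]), `params`
#'   ([model_params()]), `posterior` ([increment_posterior()]), `surface`
#'   (denoised [tfr()]), `trace` (EM trace), `ts`, and the call settings in
#'   `config`.
#' @seealso [denoised_spectrogram()], [extract_ridge()], [renyi_entropy()]
#' @export
#' @examples
#' ts <- gen_example("example1", duration = 4)
#' fit <- besct(ts, hop = 20, n_lines = 64, n_iter = 1,
#'              em = em_config(em_max = 5))
#' print(fit)
besct <- function(x, fs = NULL, window_sd = 0.5, hop = 10, n_lines = 256,
                  n_knots = 8, jump_penalty = NULL, n_iter = 3,
                  em = em_config(), kernel = NULL) {
  ts <- if (inherits(x, "time_series")) x else time_series(x, fs = fs)
  if (is.null(kernel)) {
    it <- iterate_sct(ts, n_iter = n_iter, window_sd = window_sd, hop = hop,
                      n_lines = n_lines, n_knots = n_knots,
                      jump_penalty = jump_penalty)
    kernel <- it$kernel
    rms <- it$rms
  } else rms <- numeric(0)
  grid <- interval_grid(length(ts$values), hop)
  obs <- build_observations(ts, grid, kernel = kernel,
                            window_sd = window_sd, n_lines = n_lines)
  fit <- run_em(obs, em)
  surface <- denoised_spectrogram(fit$posterior)
  sct_tfr <- tfr(obs$times, obs$freqs, obs$Y)
  structure(list(kernel = kernel, sct = sct_tfr, obs = obs,
                 params = fit$params, posterior = fit$posterior,
                 surface = surface, trace = fit$trace, ts = ts,
                 ridge_rms = rms,
                 config = list(window_sd = window_sd, hop = hop,
                               n_lines = n_lines, n_knots = n_knots,
                               n_iter = n_iter, em = em)),
            class = "besct")
}

#' @export
print.besct <- function(x, ...) {
  cat("Bayesian-embedded spline-kerneled chirplet spectrogram\n")
  cat(sprintf("  record: %d samples @ %g Hz\n",
              length(x$ts$values), x$ts$fs))
  cat(sprintf("  grid:   S = %d frequency lines x I = %d intervals (J = %d)\n",
              nrow(x$obs$Y), ncol(x$obs$Y), x$obs$grid$J))
  cat(sprintf("  EM:     %d iterations, sigma_eps2 = %.4g\n",
              nrow(x$trace), x$params$sigma_eps2))
  invisible(x)
}

#' @export
summary.besct <- function(object, ...) {
  r <- extract_ridge(object$surface)
  ans <- list(
    n = length(object$ts$values), fs = object$ts$fs,
    S = nrow(object$obs$Y), I = ncol(object$obs$Y),
    em_iterations = nrow(object$trace),
    sigma_eps2 = object$params$sigma_eps2,
    sigma_v2 = summary(object$params$sigma_v2),
    entropy_sct = renyi_entropy(object$sct),
    entropy_surface = renyi_entropy(object$surface),
    ridge = r)
  class(ans) <- "summary.besct"
  ans
}

#' @export
print.summary.besct <- function(x, ...) {
  cat("BE-SCT fit summary\n")
  cat(sprintf("  %d samples @ %g Hz; S = %d x I = %d\n", x$n, x$fs, x$S, x$I))
  cat(sprintf("  EM iterations: %d; sigma_eps2 = %.4g\n",
              x$em_iterations, x$sigma_eps2))
  cat("  sigma_v2:\n"); print(x$sigma_v2)
  cat(sprintf("  Renyi entropy (order 3): SCT %.3f -> denoised %.3f bits\n",
              x$entropy_sct, x$entropy_surface))
  cat(sprintf("  ridge: %.3g-%.3g Hz over %d columns\n",
              min(x$ridge$freq_hz), max(x$ridge$freq_hz), nrow(x$ridge)))
  invisible(x)
}

#' @export
coef.besct <- function(object, ...) {
  list(sigma_eps2 = object$params$sigma_eps2,
       sigma_v2 = object$params$sigma_v2,
       z0 = object$params$z0, sigma02 = object$params$sigma02)
}

#' @export
fitted.besct <- function(object, ...) object$surface

#' @export
residuals.besct <- function(object, ...) {
  object$obs$Y - object$posterior$sm_mean
}

#' @export
logLik.besct <- function(object, ...) {
  ll <- penalized_loglik(object$obs, object$params, object$config$em)
  attr(ll, "df") <- length(object$params$sigma_v2) + 1L
  class(ll) <- "logLik"
  ll
}

#' @export
plot.besct <- function(x, which = c("surface", "sct", "trace"), ...) {
  which <- match.arg(which)
  if (which == "trace") {
    graphics::plot(x$trace$iteration, x$trace$penalized_loglik, type = "b",
                   xlab = "EM iteration", ylab = "penalized log-likelihood",
                   ...)
  } else {
    plot(if (which == "surface") x$surface else x$sct,
         main = if (which == "surface") "BE-SCT surface" else "SCT", ...)
  }
  invisible(x)
}

#' @export
simulate.besct <- function(object, nsim = 1, seed = NULL, ...) {
  sample_posterior(object$posterior, n_draws = nsim, seed = seed)
}
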