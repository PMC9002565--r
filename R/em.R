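#' Joint posterior of the spectral increments
#'
#' Runs the forward complex Kalman filter, fixed-interval smoother and
#' lag-one covariance recursion on every frequency line of a spectral
#' observation matrix under given model parameters.
#'
#' @param obs a [build_observations()] result, or a bare complex S x I
#'   matrix.
#' @param params a [model_params()].
#' @return An object of class `"increment_posterior"`: list with S x I
#'   matrices `pred_mean`, `pred_var`, `filt_mean`, `filt_var`, `gain`,
#'   `sm_mean`, `sm_var`, `A`, `lag1` (column i of `A`/`lag1` refer to the
#'   gain from and covariance with state i-1), S-vectors `sm_mean0`,
#'   `sm_var0` for the i = 0 state, and the `freqs`/`times` grid when `obs`
#'   carries one. The invariants `0 <= gain < 1` and
#'   `sm_var <= filt_var <= pred_var` hold elementwise.
#' @export
increment_posterior <- function(obs, params) {
  Y <- if (inherits(obs, "spectral_obs")) obs$Y else as.matrix(obs)
  stopifnot(inherits(params, "model_params"), nrow(Y) == length(params$sigma_v2))
  f <- ss_filter(Y, params)
  sm <- ss_smooth(f)
  structure(list(
    pred_mean = f$pred_mean, pred_var = f$pred_var, gain = f$gain,
    filt_mean = f$filt_mean[, -1L, drop = FALSE],
    filt_var = f$filt_var[, -1L, drop = FALSE],
    filt_mean0 = f$filt_mean[, 1L], filt_var0 = f$filt_var[, 1L],
    sm_mean = sm$sm_mean[, -1L, drop = FALSE],
    sm_var = sm$sm_var[, -1L, drop = FALSE],
    sm_mean0 = sm$sm_mean[, 1L], sm_var0 = sm$sm_var[, 1L],
    A = sm$A, lag1 = sm$lag1,
    freqs = if (inherits(obs, "spectral_obs")) obs$freqs,
    times = if (inherits(obs, "spectral_obs")) obs$times),
    class = "increment_posterior")
}

#' @export
print.increment_posterior <- function(x, ...) {
  cat(sprintf("<increment_posterior> S = %d lines x I = %d intervals\n",
              nrow(x$sm_mean), ncol(x$sm_mean)))
  invisible(x)
}

#' Joint posterior draws by forward-filter backward-sampling
#'
#' Samples full trajectories `DeltaZ_{1..I,s}` per line from the joint
#' Gaussian posterior, with circularly symmetric complex innovations.
#'
#' @param posterior an [increment_posterior()].
#' @param n_draws number of joint draws (>= 1).
#' @param seed optional integer seed (isolated from the caller's RNG).
#' @return complex array `[S, I, n_draws]`.
#' @export
sample_posterior <- function(posterior, n_draws = 1000, seed = NULL) {
  stopifnot(inherits(posterior, "increment_posterior"), n_draws >= 1)
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (had) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  S <- nrow(posterior$sm_mean); I <- ncol(posterior$sm_mean)
  draws <- array(0i, c(S, I, n_draws))
  crnorm <- function(n, var) {
    sd <- sqrt(pmax(var, 0) / 2)
    complex(real = stats::rnorm(n, sd = sd),
            imaginary = stats::rnorm(n, sd = sd))
  }
  for (d in seq_len(n_draws)) {
    z <- matrix(0i, S, I)
    z[, I] <- posterior$filt_mean[, I] + crnorm(S, posterior$filt_var[, I])
    if (I > 1L) for (i in (I - 1L):1L) {
      a <- posterior$A[, i + 1L]          # gain from state i
      m <- posterior$filt_mean[, i] +
        a * (z[, i + 1L] - posterior$pred_mean[, i + 1L])
      v <- posterior$filt_var[, i] * (1 - a)
      z[, i] <- m + crnorm(S, v)
    }
    draws[, , d] <- z
  }
  draws
}

#' Denoised time-frequency surface
#'
#' The empirical-Bayes spectrogram: smoothed posterior means of the spectral
#' increments arranged on the observation grid.
#'
#' @param posterior an [increment_posterior()] built from a
#'   [build_observations()] object (so it carries the grid).
#' @return a [tfr()].
#' @export
denoised_spectrogram <- function(posterior) {
  stopifnot(inherits(posterior, "increment_posterior"))
  if (is.null(posterior$freqs))
    stop("posterior carries no frequency grid; build it from spectral_obs")
  tfr(posterior$times, posterior$freqs, posterior$sm_mean)
}

# --- EM -------------------------------------------------------------------

#' EM configuration
#'
#' @param alpha gamma-prior shape on the precisions (> 1, default 3).
#' @param beta gamma-prior rate (> 0, default 1e-3).
#' @param em_max maximum EM iterations (default 50).
#' @param eps convergence threshold on the relative change of the smoothed
#'   increments, in (0, 0.001] (default 1e-4).
#' @return list of class `"em_config"`.
#' @export
em_config <- function(alpha = 3, beta = 1e-3, em_max = 50, eps = 1e-4) {
  stopifnot(alpha > 1, beta > 0, eps > 0, eps <= 0.001)
  if (em_max < 1) stop("`em_max` must be >= 1")
  structure(list(alpha = alpha, beta = beta, em_max = as.integer(em_max),
                 eps = eps),
            class = "em_config")
}

#' Initial parameters from the data
#'
#' Initial states are the first-interval spectral coefficients and the
#' initial variances their squared moduli (elementwise); the noise and
#' innovation variances are seeded from the overall coefficient variance,
#' split evenly.
#'
#' @param obs a [build_observations()] result or complex S x I matrix.
#' @param config an [em_config()] (floors only; kept for interface
#'   symmetry).
#' @return a [model_params()].
#' @export
init_params <- function(obs, config = em_config()) {
  Y <- if (inherits(obs, "spectral_obs")) obs$Y else as.matrix(obs)
  z0 <- Y[, 1L]
  sigma02 <- pmax(Mod(z0)^2, .var_floor)
  v <- stats::var(c(Mod(Y)))
  if (!is.finite(v) || v <= 0) v <- 1
  model_params(sigma_eps2 = v / 2,
               sigma_v2 = rep(v / 2, nrow(Y)),
               z0 = z0, sigma02 = sigma02)
}

#' E-step sufficient statistics
#'
#' Posterior second moments of the increments under the current parameters:
#' `W1[i,s] = E|DeltaZ_i|^2 = |DeltaZ_{i|I}|^2 + sigma2_{i|I}` and
#' `Wx[i,s] = E[DeltaZ_i conj(DeltaZ_{i-1})] =
#' DeltaZ_{i|I} conj(DeltaZ_{i-1|I}) + sigma_{i-1,i|I}`, for i = 0..I
#' (W1) and i = 1..I (Wx), where the i = 0 state is the smoothed initial
#' state.
#'
#' @param obs observations (as in [increment_posterior()]).
#' @param params a [model_params()].
#' @return list with S x (I+1) matrix `W1`, S x I complex matrix `Wx`, the
#'   posterior, and the observation matrix.
#' @export
e_step <- function(obs, params) {
  post <- increment_posterior(obs, params)
  sm_all <- cbind(post$sm_mean0, post$sm_mean)
  sv_all <- cbind(post$sm_var0, post$sm_var)
  W1 <- Mod(sm_all)^2 + sv_all
  I <- ncol(post$sm_mean)
  Wx <- sm_all[, -1L, drop = FALSE] * Conj(sm_all[, -(I + 1L), drop = FALSE]) +
    post$lag1
  Y <- if (inherits(obs, "spectral_obs")) obs$Y else as.matrix(obs)
  list(W1 = W1, Wx = Wx, posterior = post, Y = Y)
}

#' M-step closed-form variance updates
#'
#' Maximum a posteriori precisions under the gamma prior, from the expected
#' complete-data log-likelihood. Per line s, with
#' `SS_v = sum_{i=1}^I (W1_i + W1_{i-1} - 2 Re Wx_i)` (the expected sum of
#' squared increments), `tau_v = (I + alpha - 1) / (SS_v + beta)`; and with
#' `SS_eps = sum_{i,s} (|Y|^2 + W1_i - 2 Re(conj(Y) DeltaZ_{i|I}))`,
#' `tau_eps = (S*I + alpha - 1) / (SS_eps + beta)`. Variances are the
#' reciprocals, floored; initial state and variance are carried over
#' unchanged (they are fixed by the data, not re-estimated).
#'
#' @param stats an [e_step()] result.
#' @param config an [em_config()].
#' @return a [model_params()].
#' @export
m_step <- function(stats, config = em_config()) {
  W1 <- stats$W1; Wx <- stats$Wx; post <- stats$posterior; Y <- stats$Y
  S <- nrow(Y); I <- ncol(Y)
  ss_v <- rowSums(W1[, -1L, drop = FALSE]) +
    rowSums(W1[, -(I + 1L), drop = FALSE]) - 2 * rowSums(Re(Wx))
  ss_v <- pmax(ss_v, 0)
  tau_v <- (I + config$alpha - 1) / (ss_v + config$beta)
  ss_eps <- sum(Mod(Y)^2) + sum(W1[, -1L, drop = FALSE]) -
    2 * sum(Re(Conj(Y) * post$sm_mean))
  ss_eps <- max(ss_eps, 0)
  tau_eps <- (S * I + config$alpha - 1) / (ss_eps + config$beta)
  model_params(sigma_eps2 = 1 / tau_eps, sigma_v2 = 1 / tau_v,
               z0 = post$filt_mean0, sigma02 = post$filt_var0)
}

# Expected penalized complete-data log-likelihood in the precisions, up to
# terms constant in (tau_eps, tau_v): the objective the M-step maximizes.
expected_penalized_q <- function(stats, params, config) {
  W1 <- stats$W1; Wx <- stats$Wx; Y <- stats$Y
  S <- nrow(Y); I <- ncol(Y)
  tau_v <- 1 / params$sigma_v2
  tau_eps <- 1 / params$sigma_eps2
  ss_v <- pmax(rowSums(W1[, -1L, drop = FALSE]) +
                 rowSums(W1[, -(I + 1L), drop = FALSE]) -
                 2 * rowSums(Re(Wx)), 0)
  ss_eps <- max(sum(Mod(Y)^2) + sum(W1[, -1L, drop = FALSE]) -
                  2 * sum(Re(Conj(Y) * stats$posterior$sm_mean)), 0)
  sum((I + config$alpha - 1) * log(tau_v) - tau_v * (ss_v + config$beta)) +
    (S * I + config$alpha - 1) * log(tau_eps) -
    tau_eps * (ss_eps + config$beta)
}

#' Penalized observed-data log-likelihood
#'
#' Marginal complex-Gaussian log-likelihood of the observations under the
#' random-walk model (computed line by line from the filter's one-step
#' prediction errors) plus the gamma-prior log densities of the precisions.
#' This is the quantity EM increases monotonically.
#'
#' @param obs observations (as in [increment_posterior()]).
#' @param params a [model_params()].
#' @param config an [em_config()].
#' @return scalar log-likelihood.
#' @export
penalized_loglik <- function(obs, params, config = em_config()) {
  Y <- if (inherits(obs, "spectral_obs")) obs$Y else as.matrix(obs)
  f <- ss_filter(Y, params)
  # innovations Y_i - pred_mean_i ~ CN(0, sigma_eps2 + pred_var_i)
  vv <- params$sigma_eps2 + f$pred_var
  ll <- -sum(log(pi * vv)) - sum(Mod(Y - f$pred_mean)^2 / vv)
  lprior <- function(tau) config$alpha * log(config$beta) -
    lgamma(config$alpha) + (config$alpha - 1) * log(tau) - config$beta * tau
  ll + sum(lprior(1 / params$sigma_v2)) + lprior(1 / params$sigma_eps2)
}

#' Empirical-Bayes fit of the state-space spectrogram model
#'
#' Alternates [e_step()] and [m_step()] from [init_params()] until the
#' relative Euclidean-norm change of the smoothed increments,
#' `||DeltaZ^(it) - DeltaZ^(it-1)|| / ||DeltaZ^(it-1)||` summed over all
#' lines and intervals, drops below `eps`, or `em_max` iterations are
#' reached. The returned posterior is recomputed under the final
#' parameters.
#'
#' @param obs a [build_observations()] result or complex S x I matrix.
#' @param config an [em_config()].
#' @return list with `params` ([model_params()]), `posterior`
#'   ([increment_posterior()]) and `trace` (data frame per iteration:
#'   `iteration`, `sigma_eps2`, `mean_sigma_v2`, `delta` (convergence
#'   statistic), `penalized_loglik`).
#' @export
run_em <- function(obs, config = em_config()) {
  params <- init_params(obs, config)
  prev_sm <- NULL
  rows <- vector("list", config$em_max)
  for (it in seq_len(config$em_max)) {
    stats <- e_step(obs, params)
    params <- m_step(stats, config)
    sm <- stats$posterior$sm_mean
    delta <- if (is.null(prev_sm)) Inf else
      sqrt(sum(Mod(sm - prev_sm)^2) / max(sum(Mod(prev_sm)^2), .var_floor))
    rows[[it]] <- data.frame(
      iteration = it, sigma_eps2 = params$sigma_eps2,
      mean_sigma_v2 = mean(params$sigma_v2), delta = delta,
      penalized_loglik = penalized_loglik(obs, params, config))
    prev_sm <- sm
    if (delta < config$eps) break
  }
  trace <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  list(params = params, posterior = increment_posterior(obs, params),
       trace = trace)
}

#' Export an EM trace as CSV
#' @param trace the `trace` element of [run_em()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_em_trace <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
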