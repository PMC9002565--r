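# Per-line complex Kalman filtering / smoothing on spectral observations

test_that("spectral observations follow the grid and the signal", {
  ts <- gen_example("example1", duration = 4)
  g <- interval_grid(length(ts$values), 20)
  z <- time_series(rep(0, 401), fs = 100)
  expect_true(all(Mod(build_observations(z, g, n_lines = 32)$Y) == 0))
  tt <- seq(0, 4, by = 0.01)
  tone <- time_series(sin(2 * pi * 20 * tt), fs = 100)
  obs <- build_observations(tone, g, n_lines = 64)
  expect_equal(dim(obs$Y), c(64L, g$I))
  line <- which.min(abs(obs$freqs - 20))
  mags <- Mod(obs$Y[line, ])
  inner <- mags[5:(g$I - 4)]      # away from record-boundary truncation
  expect_lt(diff(range(inner)) / mean(inner), 0.15)
  expect_error(build_observations(tone, interval_grid(2000, 20)), "fit")
  expect_error(interval_grid(30, 20), "2 intervals")
})

test_that("filter matches degenerate limits and the batch oracle", {
  set.seed(21)
  y <- rand_cplx(6)
  # zero prior and innovation variance: gain 0, mean frozen at z0
  p0 <- model_params(1, 1e-12, 0.3 + 0.1i, 0)
  f0 <- kalman_filter_line(y, p0)
  expect_true(all(f0$gain < 1e-9))
  expect_equal(f0$filt_mean, rep(0.3 + 0.1i, 6), tolerance = 1e-9)
  # vanishing observation noise: gain -> 1, mean -> data
  p1 <- model_params(1e-12, 0.5, 0i, 0.2)
  f1 <- kalman_filter_line(y, p1)
  expect_true(all(f1$gain > 1 - 1e-9))
  expect_equal(f1$filt_mean, y, tolerance = 1e-5)
  # exact agreement with the joint-Gaussian solve
  for (rep in 1:10) {
    I <- sample(2:6, 1)
    y <- rand_cplx(I)
    se <- runif(1, 0.1, 2); sv <- runif(1, 0.1, 2)
    z0 <- rand_cplx(1); s0 <- runif(1, 0, 2)
    f <- kalman_filter_line(y, model_params(se, sv, z0, s0))
    o <- batch_posterior(y, se, sv, z0, s0)
    expect_equal(f$filt_mean, o$filt_mean, tolerance = 1e-10)
    expect_equal(f$filt_var, o$filt_var, tolerance = 1e-10)
    expect_true(all(f$gain >= 0 & f$gain < 1))
  }
})

test_that("smoother and lag covariances match the batch oracle", {
  set.seed(22)
  for (rep in 1:10) {
    I <- sample(3:8, 1)
    y <- rand_cplx(I)
    se <- runif(1, 0.1, 2); sv <- runif(1, 0.1, 2)
    z0 <- rand_cplx(1); s0 <- runif(1, 0, 2)
    f <- kalman_filter_line(y, model_params(se, sv, z0, s0))
    sm <- smooth_line(f)
    o <- batch_posterior(y, se, sv, z0, s0)
    # smoothed value at i = I equals the filtered one (initialization)
    expect_equal(sm$sm_mean[I], f$filt_mean[I], tolerance = 1e-12)
    expect_equal(sm$sm_mean, o$sm_mean, tolerance = 1e-10)
    expect_equal(sm$sm_var, o$sm_var, tolerance = 1e-10)
    expect_equal(sm$sm_mean0, o$sm_mean0, tolerance = 1e-10)
    lag <- lag_covariances(sm)
    expect_equal(lag, o$lag1, tolerance = 1e-10)
    # Cauchy-Schwarz and variance orderings
    v_all <- c(sm$sm_var0, sm$sm_var)
    expect_true(all(abs(lag) <= sqrt(v_all[-(I + 1)] * v_all[-1]) + 1e-12))
    expect_true(all(sm$sm_var <= f$filt_var + 1e-12))
    expect_true(all(f$filt_var <= f$pred_var + 1e-12))
    # general covariance recursion against the oracle
    iu <- c(sample(0:(I - 2), 1), I - 1)
    expect_equal(cov_between(sm, iu[1], iu[2]),
                 o$cov[iu[1] + 1, iu[2] + 1], tolerance = 1e-8)
  }
})

test_that("a frozen random walk shrinks every interval to one state", {
  set.seed(23)
  y <- rand_cplx(8)
  p <- model_params(0.5, 1e-12, 0.2 - 0.4i, 1.5)
  sm <- smooth_line(kalman_filter_line(y, p))
  expect_lt(max(Mod(diff(sm$sm_mean))), 1e-5)
  # oracle: precision-weighted complex least squares of prior and data
  est <- (0.2 - 0.4i) / 1.5 + sum(y) / 0.5
  est <- est / (1 / 1.5 + 8 / 0.5)
  expect_equal(sm$sm_mean[1], est, tolerance = 1e-5)
})

test_that("posterior sampling reproduces the smoother moments", {
  set.seed(24)
  I <- 5
  y <- rand_cplx(I)
  p <- model_params(0.4, 0.8, 0.1 + 0.2i, 0.5)
  post <- increment_posterior(matrix(y, 1), p)
  # zero-variance posterior: draws collapse onto the smoothed mean
  pz <- model_params(1e6, 1e-12, 0.3i, 0)
  postz <- increment_posterior(matrix(y, 1), pz)
  dz <- sample_posterior(postz, n_draws = 3, seed = 1)
  expect_equal(as.vector(dz[1, , 1]), as.vector(postz$sm_mean[1, ]),
               tolerance = 1e-4)
  n <- 10000
  d <- sample_posterior(post, n_draws = n, seed = 2)
  mu_hat <- apply(d[1, , ], 1, mean)
  se <- sqrt(post$sm_var[1, ] / n)
  expect_true(all(Mod(mu_hat - post$sm_mean[1, ]) < 3 * sqrt(2) * se))
  # lag-one sample covariance vs the recursion
  for (i in 1:(I - 1)) {
    ci <- d[1, i, ] - post$sm_mean[1, i]
    cj <- d[1, i + 1, ] - post$sm_mean[1, i + 1]
    # circular complex covariance: E[ci * conj(cj)] is real here
    sc <- mean(Re(ci * Conj(cj)))
    expect_lt(abs(sc - post$lag1[1, i + 1]), 6 / sqrt(n))
  }
})

test_that("the denoised spectrogram is the smoothed-mean surface", {
  ts <- gen_example("example1", duration = 4)
  g <- interval_grid(401, 20)
  obs <- build_observations(ts, g, n_lines = 32)
  p <- init_params(obs)
  post <- increment_posterior(obs, p)
  surf <- denoised_spectrogram(post)
  expect_s3_class(surf, "tfr")
  expect_equal(dim(surf$coeffs), dim(obs$Y))
  expect_equal(surf$coeffs, post$sm_mean)
  z <- build_observations(time_series(rep(0, 401), 100), g, n_lines = 32)
  postz <- increment_posterior(z, init_params(z))
  expect_true(all(Mod(denoised_spectrogram(postz)$coeffs) < 1e-9))
})
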