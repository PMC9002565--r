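# Short-time and chirplet transforms

test_that("stft is linear and localizes a tone to one bin", {
  tt <- seq(0, 5, by = 0.01)
  tone <- time_series(sin(2 * pi * 10 * tt), fs = 100)
  z <- time_series(rep(0, length(tt)), fs = 100)
  expect_true(all(Mod(stft(z, n_lines = 64)$coeffs) == 0))
  X <- stft(tone, n_lines = 128)
  am <- X$freqs[apply(Mod(X$coeffs), 2, which.max)]
  binw <- diff(X$freqs[1:2])
  expect_true(all(abs(am - 10) <= binw))
  # linearity
  other <- time_series(cos(2 * pi * 17 * tt), fs = 100)
  both <- time_series(tone$values + other$values, fs = 100)
  expect_equal(stft(both, n_lines = 64)$coeffs,
               stft(tone, n_lines = 64)$coeffs +
                 stft(other, n_lines = 64)$coeffs,
               tolerance = 1e-9)
  expect_error(stft(time_series(rnorm(50), fs = 100)), "signal too short")
})

test_that("sct with a zero kernel reproduces stft exactly", {
  ts <- noisy_example1()
  zk <- constant_kernel(0, 0, 10)
  expect_equal(kernel_eval(zk, seq(0, 10, 0.5)), rep(0, 21), tolerance = 1e-12)
  expect_identical(sct(ts, NULL, n_lines = 64)$coeffs,
                   stft(ts, n_lines = 64)$coeffs)
})

test_that("a matched kernel concentrates a chirp on its IF ridge", {
  tt <- seq(0, 10, by = 0.01)
  chirp <- time_series(sin(2 * pi * (10 * tt + tt^2)), fs = 100)  # IF 10+2t
  track <- cbind(tt[seq(1, 1001, 50)], 10 + 2 * tt[seq(1, 1001, 50)])
  k <- fit_spline_kernel(track, 6)
  X <- sct(chirp, k)
  r <- extract_ridge(X, 0)
  binw <- diff(X$freqs[1:2])
  expect_true(all(abs(r$freq_hz - (10 + 2 * r$time_s)) <= binw))
  # demodulation oracle: multiplying by the conjugate chirp leaves a tone
  z <- analytic_signal(chirp$values)
  demod <- z * exp(-2i * pi * (10 * tt + tt^2))
  spec <- Mod(fft(demod))
  expect_lt(which.max(spec[1:500]), 6)  # energy collapsed near DC
  # and the SCT is sharper than the STFT
  expect_lt(renyi_entropy(X), renyi_entropy(stft(chirp)))
})

test_that("kernels above Nyquist warn but do not fail", {
  ts <- gen_example("example2", duration = 4)
  k <- constant_kernel(80, 0, 4)
  expect_warning(sct(ts, k, n_lines = 32), "Nyquist")
})

test_that("ridge extraction solves the stated DP objective exactly", {
  # single tone: constant track
  tt <- seq(0, 4, by = 0.01)
  tone <- time_series(sin(2 * pi * 20 * tt), fs = 100)
  X <- stft(tone, n_lines = 64)
  r <- extract_ridge(X)
  expect_equal(length(unique(r$bin)), 1L)
  expect_lt(abs(r$freq_hz[1] - 20), diff(X$freqs[1:2]))
  # two tones, one 10x stronger: track follows the stronger
  two <- time_series(sin(2 * pi * 30 * tt) + 0.1 * sin(2 * pi * 12 * tt),
                     fs = 100)
  r2 <- extract_ridge(stft(two, n_lines = 64))
  expect_true(all(abs(r2$freq_hz - 30) < 1))
  # penalty 0 reduces to columnwise argmax
  set.seed(4)
  A <- matrix(runif(40), 8, 5)
  x <- tfr(1:5, 1:8, A)
  expect_equal(extract_ridge(x, 0)$bin,
               unname(apply(A, 2, which.max)))
  # exhaustive enumeration agrees on tiny random instances
  for (rep in 1:20) {
    S <- sample(2:6, 1); I <- sample(2:6, 1)
    A <- matrix(runif(S * I), S, I)
    lam <- runif(1, 0, 0.6)
    got <- extract_ridge(tfr(1:I, 1:S, A), lam)
    oracle <- ridge_enumerate(A, lam)
    got_score <- sum(A[cbind(got$bin, 1:I)]) - lam * sum(abs(diff(got$bin)))
    expect_equal(got_score, oracle$best, tolerance = 1e-12)
  }
  expect_error(extract_ridge(tfr(1:3, 1:2, matrix(0, 2, 3))), "no ridge")
})

test_that("spline kernel fitting is least squares with nested refinement", {
  tt <- seq(0, 10, by = 0.1)
  const <- cbind(tt, rep(34.2, length(tt)))
  k <- fit_spline_kernel(const, 5)
  expect_equal(kernel_eval(k, c(0, 3.3, 10)), rep(34.2, 3), tolerance = 1e-9)
  expect_lt(k$residual_rms, 1e-9)
  # a cubic polynomial is inside the model class
  cub <- cbind(tt, 5 + 2 * tt - 0.3 * tt^2 + 0.02 * tt^3)
  expect_lt(fit_spline_kernel(cub, 4)$residual_rms, 1e-8)
  # residual non-increasing along a nested knot sequence (2^k + 1 points)
  set.seed(2)
  wig <- cbind(tt, 25 + 10 * cos(tt) + rnorm(length(tt), sd = 0.3))
  res <- sapply(c(2, 3, 5, 9), function(n)
    fit_spline_kernel(wig, n)$residual_rms)
  expect_true(all(diff(res) <= 1e-9))
  expect_error(fit_spline_kernel(cbind(rep(1, 10), 1:10), 2), "degenerate")
})

test_that("iterated refinement recovers the IF of the benchmark signal", {
  # pure tone converges immediately to a constant kernel
  tt <- seq(0, 4, by = 0.01)
  tone <- time_series(sin(2 * pi * 20 * tt), fs = 100)
  it1 <- iterate_sct(tone, n_iter = 1, n_lines = 128, n_knots = 4)
  expect_lt(max(abs(kernel_eval(it1$kernel, tt) - 20)), 0.5)
  # noiseless benchmark restricted to the pure-tone segment
  s <- gen_example("example1")
  seg <- time_series(s$values[601:1001], fs = 100, start_time = 6)
  it2 <- iterate_sct(seg, n_iter = 2, n_knots = 4)
  expect_lt(max(abs(kernel_eval(it2$kernel, seq(6, 10, 0.1)) - 34.2)), 0.5)
  # full noiseless record: ridge within 0.5 Hz at >= 95% of columns away
  # from the t = 6 s discontinuity, and the convergence diagnostic does
  # not increase
  it3 <- iterate_sct(s, n_iter = 3)
  r <- it3$ridge
  keep <- abs(r$time_s - 6) > 0.5
  err <- abs(r$freq_hz - true_if("example1", r$time_s))
  expect_gte(mean(err[keep] <= 0.5), 0.95)
  expect_true(all(diff(it3$rms) <= 1e-6))
})

test_that("Renyi entropy measures concentration", {
  one <- tfr(1:2, 1:2, matrix(c(3, 0, 0, 0), 2, 2))
  expect_equal(renyi_entropy(one), 0)
  unif <- tfr(1:4, 1:4, matrix(1, 4, 4))
  expect_equal(renyi_entropy(unif), log2(16))
  expect_error(renyi_entropy(tfr(1:2, 1:2, matrix(0, 2, 2))), "zero-energy")
})

test_that("TFR CSV pair round-trips the complex surface", {
  set.seed(9)
  x <- tfr(seq(0, 1, length.out = 5), c(1, 3, 7), matrix(rand_cplx(15), 3, 5))
  f <- tempfile(fileext = ".csv")
  write_tfr_csv(x, f)
  back <- read_tfr_csv(f)
  expect_equal(back$times, x$times)
  expect_equal(back$freqs, x$freqs)
  expect_equal(back$coeffs, x$coeffs, tolerance = 1e-6)
})
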