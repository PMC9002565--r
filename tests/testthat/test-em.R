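# EM estimation of the state-space variances

simulate_rw <- function(I, S, sv2, se2) {
  Z <- matrix(0i, S, I)
  z <- rand_cplx(S, sd = sqrt(sv2 / 2))
  for (i in seq_len(I)) {
    z <- z + rand_cplx(S, sd = sqrt(sv2 / 2))
    Z[, i] <- z
  }
  Z + matrix(rand_cplx(S * I, sd = sqrt(se2 / 2)), S, I)
}

test_that("initial parameters come from the first-interval coefficients", {
  z <- matrix(0i, 4, 6)
  p0 <- init_params(z)
  expect_true(all(p0$z0 == 0))
  expect_true(all(p0$sigma02 <= 1e-10))
  set.seed(31)
  Y <- rand_obs(5, 8, sd = 0.3)
  Y[3, ] <- Y[3, ] * 20                   # dominant line
  p <- init_params(Y)
  expect_equal(p$z0, Y[, 1])
  expect_equal(p$sigma02, Mod(Y[, 1])^2)
  expect_equal(which.max(p$sigma02), 3L)
  expect_gt(p$sigma_eps2, 0)
  expect_true(all(p$sigma_v2 > 0))
})

test_that("E-step second moments are consistent", {
  set.seed(32)
  Y <- rand_obs(3, 6)
  # degenerate zero-variance states: moments collapse to products of means
  pz <- model_params(1e6, 1e-12, Y[, 1], 0)
  st <- e_step(Y, pz)
  expect_equal(st$W1, Mod(cbind(st$posterior$sm_mean0,
                                st$posterior$sm_mean))^2, tolerance = 1e-6)
  # generic instance: invariants and Monte Carlo agreement
  p <- model_params(0.5, 0.7, Y[, 1], Mod(Y[, 1])^2)
  st <- e_step(Y, p)
  sm_all <- cbind(st$posterior$sm_mean0, st$posterior$sm_mean)
  expect_true(all(st$W1 >= Mod(sm_all)^2 - 1e-12))
  expect_true(all(Mod(st$Wx) <=
                    sqrt(st$W1[, -1] * st$W1[, -ncol(st$W1)]) + 1e-9))
  n <- 8000
  d <- sample_posterior(st$posterior, n_draws = n, seed = 5)
  w1_mc <- apply(Mod(d)^2, c(1, 2), mean)
  expect_true(all(abs(w1_mc - st$W1[, -1]) < 8 / sqrt(n) *
                    pmax(st$W1[, -1], 1)))
})

test_that("closed-form M-step maximizes the expected penalized likelihood", {
  set.seed(33)
  Y <- rand_obs(2, 4)
  cfg <- em_config(alpha = 3, beta = 1e-3)
  p <- init_params(Y, cfg)
  st <- e_step(Y, p)
  up <- m_step(st, cfg)
  I <- ncol(Y); S <- nrow(Y)
  # independent numeric maximization (golden section via optimize) of the
  # objective in each precision separately
  W1 <- st$W1; Wx <- st$Wx
  ss_v <- rowSums(W1[, -1, drop = FALSE]) + rowSums(W1[, -(I + 1), drop = FALSE]) -
    2 * rowSums(Re(Wx))
  for (s in 1:S) {
    f <- function(tau) (I + cfg$alpha - 1) * log(tau) -
      tau * (ss_v[s] + cfg$beta)
    opt <- optimize(f, c(1e-6, 1e3), maximum = TRUE, tol = 1e-12)
    expect_equal(1 / up$sigma_v2[s], opt$maximum, tolerance = 1e-6)
  }
  ss_e <- sum(Mod(Y)^2) + sum(W1[, -1, drop = FALSE]) -
    2 * sum(Re(Conj(Y) * st$posterior$sm_mean))
  fe <- function(tau) (S * I + cfg$alpha - 1) * log(tau) -
    tau * (ss_e + cfg$beta)
  opte <- optimize(fe, c(1e-6, 1e3), maximum = TRUE, tol = 1e-12)
  expect_equal(1 / up$sigma_eps2, opte$maximum, tolerance = 1e-6)
})

test_that("with a vanishing prior the M-step is maximum likelihood", {
  set.seed(34)
  Y <- rand_obs(3, 5)
  cfg <- em_config(alpha = 1 + 1e-9, beta = 1e-12)
  p <- init_params(Y, cfg)
  st <- e_step(Y, p)
  up <- m_step(st, cfg)
  I <- ncol(Y)
  W1 <- st$W1; Wx <- st$Wx
  ss_v <- rowSums(W1[, -1, drop = FALSE]) +
    rowSums(W1[, -(I + 1), drop = FALSE]) - 2 * rowSums(Re(Wx))
  expect_equal(up$sigma_v2, ss_v / I, tolerance = 1e-6)
  ss_e <- sum(Mod(Y)^2) + sum(W1[, -1, drop = FALSE]) -
    2 * sum(Re(Conj(Y) * st$posterior$sm_mean))
  expect_equal(up$sigma_eps2, ss_e / (nrow(Y) * I), tolerance = 1e-6)
})

test_that("EM is monotone in the penalized observed-data likelihood", {
  set.seed(35)
  for (rep in 1:5) {
    Y <- simulate_rw(sample(10:30, 1), sample(2:5, 1),
                     runif(1, 0.2, 1), runif(1, 0.05, 0.5))
    cfg <- em_config(em_max = 25)
    r <- run_em(Y, cfg)
    expect_true(all(diff(r$trace$penalized_loglik) > -1e-8))
  }
})

test_that("EM bookkeeping follows the configuration", {
  set.seed(36)
  Y <- rand_obs(2, 8)
  r1 <- run_em(Y, em_config(em_max = 1))
  expect_equal(nrow(r1$trace), 1L)
  expect_error(em_config(em_max = 0), "em_max")
  expect_error(em_config(eps = 0.1))
  r <- run_em(Y, em_config(em_max = 30))
  expect_true(all(diff(r$trace$delta[-1]) <= 1e-9))  # statistic decreases
  f <- tempfile(fileext = ".csv")
  write_em_trace(r$trace, f)
  expect_equal(nrow(utils::read.csv(f)), nrow(r$trace))
})

test_that("EM recovers known variances and is stable at the truth", {
  set.seed(37)
  res <- t(sapply(1:6, function(k) {
    Y <- simulate_rw(200, 8, 0.5, 0.1)
    r <- run_em(Y)
    c(r$params$sigma_eps2, stats::median(r$params$sigma_v2))
  }))
  expect_lt(stats::median(abs(res[, 1] - 0.1) / 0.1), 0.25)
  expect_lt(stats::median(abs(res[, 2] - 0.5) / 0.5), 0.25)
  # fixed point: one EM cycle from the truth moves parameters < 10%
  Y <- simulate_rw(400, 8, 0.5, 0.1)
  pt <- init_params(Y)
  pt$sigma_eps2 <- 0.1
  pt$sigma_v2[] <- 0.5
  p1 <- m_step(e_step(Y, pt), em_config())
  expect_lt(abs(p1$sigma_eps2 - 0.1) / 0.1, 0.1)
  expect_lt(stats::median(abs(p1$sigma_v2 - 0.5) / 0.5), 0.1)
})
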