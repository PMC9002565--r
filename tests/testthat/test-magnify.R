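# Phase-based magnification

mk_grating_clip <- function(T_ = 60, H = 32, W = 32, cycles = 5, amp = 0.3,
                            freq = 3, fps = 30) {
  fr <- array(0, c(T_, H, W))
  for (t in seq_len(T_)) {
    d <- amp * sin(2 * pi * freq * (t - 1) / fps)
    fr[t, , ] <- matrix(0.5 + 0.35 * sin(2 * pi * cycles * ((1:H) - d) / H),
                        H, W)
  }
  video_sequence(fr, fps)
}

grating_amplitude <- function(v, cycles = 5, freq = 3) {
  T_ <- dim(v$frames)[1]
  H <- dim(v$frames)[2]
  ph <- vapply(seq_len(T_), function(t)
    Arg(stats::fft(v$frames[t, , 1, 1])[cycles + 1]), numeric(1))
  for (t in 2:T_) {
    d <- (ph[t] - ph[t - 1] + pi) %% (2 * pi) - pi
    ph[t] <- ph[t - 1] + d
  }
  fit_sine_amplitude(ph, v$fps, freq) / (2 * pi * cycles / H)
}

test_that("alpha = 0 returns the input up to reconstruction error", {
  set.seed(71)
  v <- video_sequence(array(runif(8 * 32 * 32 * 3), c(8, 32, 32, 3)), 30)
  m <- magnify(v, c(2, 5), alpha = 0, levels = 2)
  expect_lt(sqrt(sum((m$frames - v$frames)^2) / sum(v$frames^2)), 1e-2)
})

test_that("a static video stays static under any alpha", {
  fr <- array(rep(outer(sin(1:24), cos(1:24)) * 0.2 + 0.5, 6),
              c(24, 24, 6))
  v <- video_sequence(aperm(fr, c(3, 1, 2)), 30)
  m <- magnify(v, c(2, 5), alpha = 8, levels = 2)
  ref <- m$frames[1, , , ]
  for (t in 2:6)
    expect_lt(max(abs(m$frames[t, , , ] - ref)), 1e-6)
})

test_that("in-band motion of a narrowband pattern scales by 1 + alpha", {
  v <- mk_grating_clip()
  for (a in c(2, 5)) {
    m <- magnify(v, c(2.5, 3.5), alpha = a, levels = 2)
    expect_equal(grating_amplitude(m), (1 + a) * 0.3, tolerance = 0.05)
  }
  # out-of-band schedule leaves the motion unamplified
  m0 <- magnify(v, c(8, 12), alpha = 5, levels = 2)
  expect_equal(grating_amplitude(m0), 0.3, tolerance = 0.05)
})

test_that("schedule validation and degenerate cases", {
  v <- mk_grating_clip(T_ = 20)
  expect_error(magnify(v, c(16, 20), alpha = 1), "Nyquist")
  empty <- data.frame(interval = integer(0), time_s = numeric(0),
                      f_low_hz = numeric(0), f_high_hz = numeric(0))
  class(empty) <- c("passband_schedule", "data.frame")
  expect_warning(m <- magnify(v, empty, alpha = 3), "empty")
  expect_equal(m$frames, v$frames)
})

test_that("measured ball vibration grows affinely with alpha", {
  b <- gen_ball_video()
  amps <- vapply(c(1, 2, 4, 8), function(a) {
    m <- magnify(b$video, c(2.5, 3.5), alpha = a)
    fit_sine_amplitude(centroid_trace(m)$y, b$video$fps, 3)
  }, numeric(1))
  expect_true(all(diff(amps) > 0))
  fit <- stats::lm(amps ~ c(1, 2, 4, 8))
  expect_gt(summary(fit)$r.squared, 0.95)
})

test_that("a time-varying schedule is honored by overlap-add filtering", {
  v <- mk_grating_clip(T_ = 90)
  sch <- data.frame(interval = rep(1:6, each = 1),
                    time_s = seq(0.25, 2.75, by = 0.5),
                    f_low_hz = c(2.5, 2.5, 2.5, 8, 8, 8),
                    f_high_hz = c(3.5, 3.5, 3.5, 12, 12, 12))
  class(sch) <- c("passband_schedule", "data.frame")
  m <- magnify(v, sch, alpha = 4, levels = 2)
  # early frames amplified, late frames not
  early <- grating_amplitude(video_sequence(m$frames[1:30, , , ], 30))
  late <- grating_amplitude(video_sequence(m$frames[61:90, , , ], 30))
  expect_gt(early, 1.8 * 0.3)
  expect_lt(late, 1.8 * 0.3)
})
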