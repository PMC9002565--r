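#' Analytic nonstationary test signals
#'
#' Two standard nonlinearly frequency-modulated benchmark signals used
#' throughout the package's tests and examples.
#'
#' `"example1"` is a sinusoidal-FM tone that switches abruptly to a pure
#' tone: `sin(2*pi*(25*t + 10*sin(t)))` for `t` in `[0, 6)` s and
#' `sin(2*pi*34.2*t)` for `t` in `[6, 10]` s (the boundary sample belongs to
#' the second segment). `"example2"` is
#' `sin(30 + 50*t + 60*t^2 + 40*sin(t))`, a quadratic-plus-sinusoidal phase
#' law written without a 2*pi factor, so its instantaneous frequency in Hz
#' is `(50 + 120*t + 40*cos(t)) / (2*pi)`; past roughly 1.9 s this exceeds
#' the Nyquist frequency of the default 100 Hz sampling rate and the
#' sampled record is aliased. The formula is evaluated literally.
#'
#' @param which `"example1"` or `"example2"`.
#' @param fs sampling rate in Hz (default 100).
#' @param duration record length in seconds (default 10).
#' @return a [time_series()] sampled on `[0, duration]` inclusive.
#' @seealso [true_if()] for the analytic instantaneous frequency,
#'   [add_noise()], [snr_db()].
#' @export
#' @examples
#' s <- gen_example("example1")
#' length(s$values)  # 1001 samples at 100 Hz over 10 s
gen_example <- function(which = c("example1", "example2"),
                        fs = 100, duration = 10) {
  which <- match.arg(which)
  stopifnot(fs > 0, duration > 0)
  t <- seq(0, duration, by = 1 / fs)
  x <- if (which == "example1") {
    ifelse(t < 6,
           sin(2 * pi * (25 * t + 10 * sin(t))),
           sin(2 * pi * 34.2 * t))
  } else {
    sin(30 + 50 * t + 60 * t^2 + 40 * sin(t))
  }
  time_series(x, fs = fs, start_time = 0)
}

#' Add white Gaussian noise to a time series
#'
#' @param ts a [time_series()].
#' @param variance noise variance in amplitude^2 (default 0.1). The noise
#'   scale is parameterized as a variance: with a unit-amplitude sinusoid
#'   (mean power 1/2) this gives an expected SNR of
#'   `10*log10(0.5/variance)`, about 7.0 dB at the default.
#' @param seed optional integer seed; when given, the draw is made under a
#'   local RNG state (the caller's RNG stream is left untouched) and is
#'   reproducible.
#' @return a [time_series()] with the same grid.
#' @export
add_noise <- function(ts, variance = 0.1, seed = NULL) {
  stopifnot(inherits(ts, "time_series"), variance >= 0)
  if (variance == 0) return(ts)
  eps <- local_rnorm(length(ts$values), sd = sqrt(variance), seed = seed)
  time_series(ts$values + eps, fs = ts$fs, start_time = ts$start_time)
}

# rnorm under an optional isolated seed
local_rnorm <- function(n, sd = 1, seed = NULL) {
  if (is.null(seed)) return(stats::rnorm(n, sd = sd))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  stats::rnorm(n, sd = sd)
}

#' Signal-to-noise ratio in dB
#'
#' `10*log10(sum(clean^2) / sum((noisy - clean)^2))` over the whole record.
#'
#' @param clean,noisy [time_series()] objects on the same grid.
#' @return SNR in dB.
#' @export
snr_db <- function(clean, noisy) {
  stopifnot(inherits(clean, "time_series"), inherits(noisy, "time_series"))
  if (length(clean$values) != length(noisy$values))
    stop("`clean` and `noisy` must have equal length")
  p_noise <- sum(Mod(noisy$values - clean$values)^2)
  if (p_noise == 0) stop("zero noise power: SNR is infinite")
  10 * log10(sum(Mod(clean$values)^2) / p_noise)
}

#' Analytic instantaneous frequency of the test signals
#'
#' The time derivative of the phase divided by 2*pi: for `"example1"`,
#' `25 + 10*cos(t)` Hz on `[0, 6)` and 34.2 Hz on `[6, 10]`; for
#' `"example2"`, `(50 + 120*t + 40*cos(t)) / (2*pi)` Hz (reported
#' unfolded, i.e. not aliased to the Nyquist band).
#'
#' @param which `"example1"` or `"example2"`.
#' @param t time(s) in seconds, within `[0, 10]`.
#' @return instantaneous frequency in Hz, vectorized over `t`.
#' @export
true_if <- function(which = c("example1", "example2"), t) {
  which <- match.arg(which)
  if (any(t < 0 | t > 10)) stop("`t` out of the [0, 10] s record")
  if (which == "example1") {
    ifelse(t < 6, 25 + 10 * cos(t), 34.2)
  } else {
    (50 + 120 * t + 40 * cos(t)) / (2 * pi)
  }
}
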