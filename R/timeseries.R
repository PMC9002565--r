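#' Uniformly sampled time series
#'
#' Light container for a uniformly sampled real- or complex-valued signal,
#' the observation model being a latent locally stationary Gaussian process
#' observed in independent Gaussian noise.
#'
#' @param values numeric or complex vector of samples (length >= 2, finite).
#' @param fs sampling rate in Hz (> 0).
#' @param start_time time of the first sample in seconds.
#'
#' @return An object of class `"time_series"`: a list with elements
#'   `values`, `fs`, `start_time`.
#' @export
#' @examples
#' ts <- time_series(sin(2 * pi * 5 * seq(0, 1, by = 0.01)), fs = 100)
#' ts_times(ts)[1:3]
time_series <- function(values, fs, start_time = 0) {
  if (!is.numeric(values) && !is.complex(values))
    stop("`values` must be numeric or complex")
  if (length(values) < 2L) stop("a time series needs at least 2 samples")
  if (!all(is.finite(values))) stop("all sample values must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number (Hz)")
  structure(list(values = as.vector(values), fs = as.numeric(fs),
                 start_time = as.numeric(start_time)),
            class = "time_series")
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<time_series> %d samples @ %g Hz, t in [%.4g, %.4g] s%s\n",
              length(x$values), x$fs, x$start_time,
              x$start_time + (length(x$values) - 1) / x$fs,
              if (is.complex(x$values)) " (complex)" else ""))
  invisible(x)
}

#' Sample times of a time series
#' @param ts a [time_series()].
#' @return numeric vector of sample times in seconds.
#' @export
ts_times <- function(ts) {
  stopifnot(inherits(ts, "time_series"))
  ts$start_time + (seq_along(ts$values) - 1) / ts$fs
}

#' Read / write a time series as CSV
#'
#' Two-column CSV with a header row `time_s,value`. The sampling rate is
#' recovered from the median time step; the grid must be uniform to within
#' one part in 1e6.
#'
#' @param path file path.
#' @param ts a [time_series()].
#' @return `read_ts_csv` returns a [time_series()]; `write_ts_csv` returns
#'   `path` invisibly.
#' @export
read_ts_csv <- function(path) {
  if (!file.exists(path)) stop("cannot read time series: no such file: ", path)
  d <- utils::read.csv(path)
  if (ncol(d) < 2L) stop("expected two columns (time_s, value) in ", path)
  tt <- as.numeric(d[[1L]])
  dt <- diff(tt)
  if (any(abs(dt - stats::median(dt)) > 1e-6 * stats::median(dt)))
    stop("time grid in ", path, " is not uniform")
  time_series(as.numeric(d[[2L]]), fs = 1 / stats::median(dt),
              start_time = tt[1L])
}

#' @rdname read_ts_csv
#' @export
write_ts_csv <- function(ts, path) {
  stopifnot(inherits(ts, "time_series"))
  d <- data.frame(time_s = ts_times(ts), value = Re(ts$values))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a single-channel 16-bit PCM WAV file
#'
#' Minimal RIFF/WAVE support for mono PCM16, enough to exchange sampled
#' signals with audio tooling. Amplitudes are scaled to [-1, 1] on read and
#' clipped to [-1, 1] on write.
#'
#' @param path file path.
#' @param ts a [time_series()] with real values.
#' @return `read_ts_wav` returns a [time_series()]; `write_ts_wav` returns
#'   `path` invisibly.
#' @export
read_ts_wav <- function(path) {
  if (!file.exists(path)) stop("cannot read WAV: no such file: ", path)
  con <- file(path, "rb"); on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1L, size = 4L, endian = "little"))
  if (!identical(readChar(con, 4L, useBytes = TRUE), "WAVE"))
    stop("not a WAVE file: ", path)
  fs <- NA_real_; bits <- NA_integer_; nchan <- NA_integer_; samples <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", sz %/% 2L, size = 2L,
                     endian = "little", signed = FALSE)
      nchan <- fmt[2L]; bits <- fmt[8L]
      fs <- fmt[3L] + 65536 * fmt[4L]
    } else if (identical(id, "data")) {
      samples <- readBin(con, "integer", sz %/% 2L, size = 2L,
                         endian = "little", signed = TRUE)
      break
    } else {
      invisible(readBin(con, "raw", sz + (sz %% 2L)))
    }
  }
  if (is.null(samples)) stop("no data chunk in ", path)
  if (!identical(as.integer(nchan), 1L) || !identical(as.integer(bits), 16L))
    stop("only mono 16-bit PCM WAV is supported")
  time_series(samples / 32767, fs = fs)
}

#' @rdname read_ts_wav
#' @export
write_ts_wav <- function(ts, path) {
  stopifnot(inherits(ts, "time_series"))
  x <- pmin(1, pmax(-1, Re(ts$values)))
  pcm <- as.integer(round(x * 32767))
  n <- length(pcm)
  con <- file(path, "wb"); on.exit(close(con))
  w32 <- function(v) writeBin(as.integer(v), con, size = 4L, endian = "little")
  w16 <- function(v) writeBin(as.integer(v), con, size = 2L, endian = "little")
  writeChar("RIFF", con, eos = NULL); w32(36L + 2L * n)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); w32(16L); w16(1L); w16(1L)
  w32(round(ts$fs)); w32(round(ts$fs) * 2L); w16(2L); w16(16L)
  writeChar("data", con, eos = NULL); w32(2L * n)
  w16(pcm)
  invisible(path)
}

#' Analytic signal via the one-sided spectrum
#'
#' Returns the complex analytic signal of a real record: the FFT is doubled
#' on strictly positive frequencies and zeroed on negative ones, so the real
#' part reproduces the input and the imaginary part is its Hilbert transform.
#' Complex inputs are returned unchanged.
#'
#' @param x numeric vector.
#' @return complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  if (is.complex(x)) return(x)
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}
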